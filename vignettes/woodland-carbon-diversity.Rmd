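---
title: "Carbon, diversity and sampling design in dry-woodland inventory plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon, diversity and sampling design in dry-woodland inventory plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miomboAGC)
```

## The problem this package addresses

Seasonally dry tropical woodlands — miombo above all — hold large but poorly
quantified stocks of aboveground woody carbon (AGC) alongside a diverse tree
flora. Permanent inventory plots in these systems typically census every stem
with diameter at breast height (DBH) of at least 5 cm in a 1-ha window,
sometimes nested centrally inside a larger window where only large stems
(over 40 cm) are recorded. From such stem tables one wants to know:

* how much carbon each plot holds and how that carbon is distributed across
  stem size classes and species (including *hyperdominance*: the smallest
  set of stems or species holding, say, half the total);
* how tree α-diversity (richness, Fisher's α, rarefied richness) and
  β-diversity (compositional turnover) co-vary with the carbon gradient;
* what a cheaper census — a higher DBH threshold, or a smaller plot —
  would have missed.

`miomboAGC` implements that analysis chain end to end, and pairs it with a
spatially explicit synthetic stand generator so every stage can be tested
against known ground truth.

## Carbon accounting

Stem biomass follows a power-law allometry `AGB (kg) = a * DBH^b`, converted
to carbon with a fixed carbon fraction (default 0.47). Coefficients are
deliberately configuration-driven (`allometry_model()`); the shipped default
(`a = 0.1027`, `b = 2.4798`) is a published Tanzanian miombo equation and
should be replaced by a local model where one exists. All package tests use
explicitly stated toy coefficients, so no conclusion depends on the default.

Size classes are half-open 5-cm bins `[lo, lo + 5)` from 5 cm upward; the
broad census classes are small `[5, 15)`, medium `[15, 40)` and large
`[40, Inf)`. Half-open intervals make boundary stems unambiguous (a 15.0-cm
stem is medium; "larger than 40 cm" is implemented as `DBH >= 40`, stated
here because the verbal convention is ambiguous). `hyperdominance()` ranks
entities by value and reports the smallest top set reaching a quantile of
the total; ties are broken by stable input order, which cannot change the
result because only cumulative sums enter the criterion.

## Diversity

`fishers_alpha(S, N)` solves `S = α log(1 + N/α)` — the log-series
relation — by bracketed root search refined to a residual below 1e-9.
`rarefy_mao_tao()` is the analytic individual-based expectation
`E[S_m] = Σ_i (1 − C(N−N_i, m)/C(N, m))`, evaluated with log-gamma
arithmetic; it equals the mean over all subsamples without replacement, and
the tests verify it against brute-force resampling and against vegan's
implementation. For the "rarefied richness" used in the biomass–diversity
regression the depth is the smallest plot total across the network
(standard practice; a fixed depth can be configured instead).

Morphospecies are verbatim labels: species, genus or local name, whichever
identification level was achieved, with fully unidentified stems excluded
from diversity analyses by default. Size-class diversity for the large class
can include the outer large-tree census; richness is then only comparable
between groups, not between size classes, because the sampled area differs.

## Composition

Raw abundances are square-root transformed and then site-standardised
(each row divided by its total) — in that order, since the order changes the
result; both steps are flags in `transform_abundance()`. Wisconsin-style
double standardisation is deliberately not the default: the stated purpose
of the row division is to remove differences in stems sampled per site.

Bray–Curtis dissimilarity, NMDS and PerMANOVA follow the standard community
ecology toolkit. `nmds()` minimises Kruskal stress-1 via vegan's `monoMDS`
engine with a classical-metric-scaling first start and seeded random
restarts, reporting the best restart and whether it converged. `permanova()`
implements the distance-based one-factor partition
(`SS_T = (1/N) Σ_{i<j} d²`, within-group sums weighted by group size) with a
label-permutation null and the add-one convention, so p is never exactly
zero and is bounded below by `1/(n_perm + 1)`; tests verify it against
exhaustive enumeration on small instances and against `vegan::adonis2`.

## Biomass–diversity model selection

Four ecologically motivated forms are fitted with AGC as the response and
diversity as the predictor (diversity is treated as the independent
variable): linear `y = ax + b`, saturating `y = ax/(b + x)`, quadratic
`y = ax² + bx + c`, and Ricker `y = ax·e^(−bx)`. Linear and quadratic are
closed-form least squares; the nonlinear forms use Levenberg–Marquardt
(`minpack.lm::nls.lm`) from data-driven starts (`a₀ = max(y)`,
`b₀ = median(x)` for saturation; `a₀ = max(y)·e/x_max`, `b₀ = 1/x_max` for
Ricker) with ten seeded, jittered restarts; non-convergence is flagged, not
hidden. Selection minimises AICc,
`n log(rss/n) + 2k + 2k(k+1)/(n−k−1)` with `k` counting the error variance;
a numerically exact fit reports `rss = 0` and `AICc = −Inf`, and ties break
toward lower RSS and then fewer parameters, so on noiseless linear data the
linear form beats the quadratic. Regression p-values are reported
unadjusted.

## Group comparisons

The distribution of carbon across size classes is compared between plot
groups with a permutation Kolmogorov–Smirnov-type statistic: each group is
summarised by its cumulative mean AGC-share curve over 5-cm bins and
`D = max |cum A − cum B|`; significance comes from permuting plot-to-group
labels. The classical two-sample KS null is *not* valid for binned,
plot-averaged shares, which is why the permutation null is the default and
only construction. Structure and diversity variables are compared with
one-way ANOVA (`stats::oneway.test`, equal variances) and Tukey's HSD
(Tukey–Kramer `q`, p from `stats::ptukey`).

## Subplot-sampling simulation

`run_subsampling()` asks what smaller plots would have measured: for each
area (default 0.1, 0.25 and 0.5 ha) and iteration (default 1000), one
axis-aligned square subplot is placed uniformly at random in every plot
(origin uniform on `[0, L − s]²`), and subplot richness and AGC density are
expressed as percentages of the full-plot values; species pooled across all
subplots give the network-level capture. Squares are a documented choice —
the shape is otherwise unspecified in field protocols — and windows are
half-open so edge stems are never double-counted. Summaries pool plot ×
iteration values; percentiles use R's default linear interpolation
(type 7). Richness capture rises with area by construction; AGC density is
unbiased under uniform placement, which the tests check both analytically
(single-centre-stem and two-quadrant constructions with known geometric
probabilities) and by Monte Carlo.

## The synthetic stand generator

`generate_stand()` draws a stem count from Poisson(target density × area),
positions from either complete spatial randomness or a Thomas cluster
process (Gaussian offspring displacement, wrapped on the window so the
realised intensity stays at target), DBH from a truncated exponential or
Weibull, and species from a log-series species-abundance distribution over
a configurable pool. Nested designs simulate the outer annulus with the
same density and size distribution but record only stems above the outer
threshold; the inner window is centred, and outer records never duplicate
inner stems. Every stand carries its ground truth (generating α, species
totals, true AGC) for parameter-recovery tests.

Two generator choices deserve emphasis:

* **Low-variance SAD realisation.** The expected number of species with
  abundance `k` under the log-series is `φ_k = α x^k / k` with
  `x = N/(N + α)`. `sample_logseries_sad()` realises these class counts by
  *systematic* rounding — one shared uniform offset across the cumulative
  expected counts — and repairs the residual mismatch with `N` on the most
  abundant species. Each abundance class is correct in expectation and the
  counts sum exactly to `N`, but realised richness is concentrated tightly
  around `α log(1 + N/α)`. A fully independent random draw would scatter
  richness with a standard deviation of about 7 species at `N = 10⁴`,
  α = 8 — enough that Fisher's α could not be recovered reliably from a
  single community. Since the generator exists to provide recoverable
  ground truth, we accept the reduced between-replicate richness variance
  and state the consequence plainly: between-plot richness spread in
  synthetic networks is much smaller than in field data, so tests that
  pass on synthetic networks say nothing about richness *variability* in
  real plots.
* **Plot-level turnover (`rank_noise_sd`).** Mapping SAD ranks onto a fixed
  pool order would make all plots of a class compositionally identical.
  Each plot therefore perturbs the pool's ranks multiplicatively by
  `exp(N(0, rank_noise_sd))` before assignment. The default (1.5) was fixed
  once so that within-class Bray–Curtis dissimilarity on transformed
  abundances falls in the 0.6–0.7 range typical of real dry-woodland plot
  networks; it also keeps the three-class NMDS stress near 0.1 rather than
  collapsing to a degenerate zero-stress clustering.

The default 25-plot network (`default_network_config()`) has three
vegetation classes — 7 sparse savanna plots (300 stems/ha, truncated
exponential DBH, α = 4), 12 savanna-woodland plots (700 stems/ha,
Weibull(0.7, 3.0), α = 7) and 6 closed woodland/forest plots (1050
stems/ha, Weibull(0.7, 3.5), α = 8) — chosen by expectation calculations to
span roughly 4–55 tC/ha with a network mean near 25 ± 17 tC/ha, about 160
morphospecies, and realistic size-class structure (roughly a fifth of stems
above 15 cm in wooded classes, large stems of 80+ cm appearing at about
one per hectare only in the densest class). Class pools share a quarter of
their species. Within-plot spatial pattern defaults to Poisson: no field
estimate of clustering was available to calibrate against, so clustering is
an explicit knob (`thomas`), not a claimed property; subplot richness
capture in synthetic networks is accordingly somewhat higher than field
studies report, where spatial aggregation makes small subplots miss more
species.

What the generator does *not* emulate: forked stems as linked records
(every stem is an independent individual), identification uncertainty,
understory layers, growth or mortality, topography, and — as noted —
realistic between-plot richness scatter and spatial clustering by default.

## Numerical conventions and degenerate inputs

* Coordinates and all sampling windows are half-open (`[0, L)`).
* Fisher's α root search brackets `[1e-6, 1e6]` with expansion; undefined
  when `S = 0` or `S ≥ N` (reported as `NA` in tables, never 0).
* Rarefaction uses `lchoose`, so impossible binomial coefficients vanish
  exactly; depths outside `[1, N]` are errors.
* All-zero abundance rows survive transformation as zeros with a warning;
  Bray–Curtis between two all-zero vectors is an error.
* Degenerate ANOVA (zero between- and within-group variance) reports an
  undefined statistic with p = 1; a fully zero distance matrix does the
  same for PerMANOVA.
* Permutation p-values use the add-one convention throughout.
* Every stochastic function takes a `seed` and restores the caller's RNG
  state; pipeline stages derive independent child seeds from the master
  seed by hashing the stage name, so adding a stage never perturbs another.

## Problem sizes used in the shipped tests

The test suite exercises the estimators at sizes chosen to make the oracles
exact or their Monte-Carlo error small: rarefaction against 20,000
brute-force subsamples on communities of up to ~200 individuals; PerMANOVA
and the KS statistic against exhaustive label enumeration on 4–6 units;
α-recovery from 100 communities of 10,000 individuals; form recovery and
selection over 200 noisy replicates of 25 points (5% noise); type-I error
of the permutation tests over 200 null simulations at 199 permutations
each; and the subplot geometry constructions at 10⁵ draws. The default
pipeline (25 plots, 1000 subplot iterations, 999 permutations) runs in a
few seconds.

## Known limitations

* The biomass–diversity fits are descriptive; nothing here supports causal
  claims, and no spatial autocorrelation or mixed-effects structure is
  modelled.
* Allometric uncertainty is not propagated; belowground carbon, height and
  wood density are out of scope.
* The KS-type comparison is defined on plot-averaged share curves; it is
  not the classical stem-level two-sample test, and its p-values are only
  as good as the permutation null (group exchangeability).
* Coverage-based rarefaction/extrapolation (Chao) and Hill numbers are not
  provided.
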