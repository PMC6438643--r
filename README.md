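# miomboAGC

Aboveground carbon, tree diversity and sampling design for stem-level
forest inventories in seasonally dry tropical woodlands (miombo and
similar systems).

Permanent sample plots in these landscapes census every stem with DBH ≥
5 cm in a 1-ha window, sometimes nested inside a larger window recording
only large stems (≥ 40 cm). `miomboAGC` turns such stem tables into the
standard analysis products of a woodland carbon–biodiversity study:

* **Carbon accounting** — per-stem AGC from a power-law allometry
  (AGB kg = a·DBH^b, carbon fraction 0.47 by default), plot AGC densities
  (tC ha⁻¹), 5-cm size-class carbon distributions, **hyperdominance**
  (the smallest set of stems or species holding half the carbon), species
  dominance rankings, and the sensitivity of inventory totals to the
  minimum-DBH census threshold.
* **α-diversity** — species richness, Fisher's α (the root of
  S = α·ln(1 + N/α)), and analytic individual-based (Mao-Tau-type)
  rarefaction E[S_m] = Σᵢ (1 − C(N−Nᵢ, m)/C(N, m)), overall and per size
  class.
* **β-diversity** — square-root + site-standardised abundances,
  Bray–Curtis distances, NMDS (Kruskal stress-1, best-of-restarts),
  one-factor PerMANOVA with a permutation null, within-group
  dissimilarity summaries and group-unique species counts.
* **Biomass–diversity model selection** — linear, saturating
  (y = ax/(b+x)), quadratic and Ricker (y = ax·e^(−bx)) forms fitted by
  (nonlinear) least squares and compared by small-sample AICc.
* **Group tests** — permutation KS comparison of size-class carbon
  curves, one-way ANOVA and Tukey HSD.
* **Subplot-sampling simulation** — randomly placed square subplots
  (0.1 / 0.25 / 0.5 ha by default, 1000 iterations) quantifying how much
  plot-level richness and AGC density smaller plots would have captured.
* **Synthetic stand generator** — spatially explicit, species-labelled
  stands (log-series abundances, Poisson or Thomas-cluster placement,
  truncated exponential/Weibull DBH, nested large-tree windows) with
  known ground truth, so the whole pipeline is testable without field
  data.

## Worked example

Simulate the default 25-plot, three-class network and run the full
analysis:

```r
library(miomboAGC)

cfg <- pipeline_config(seed = 42, n_subplot_iterations = 200)
report <- run_pipeline(cfg, outdir = "run42", verbose = FALSE)
report
#> Inventory report: 25 plots, mean AGC 25.3 +/- 16.0 tC/ha (range 4.3-55.3)
#> Half of stem AGC in the 879 largest stems (5.2% of stems)
#> Best biomass-diversity form: ricker; richness OLS r2 = 0.91
#> NMDS stress = 0.076 (k = 3); PerMANOVA p = 0.001
```

So this synthetic landscape stores on average 25.3 tC ha⁻¹ (spanning
sparse savanna at 4 tC ha⁻¹ to closed woodland at 55 tC ha⁻¹), half its
woody carbon sits in just 5.2% of stems, richness explains ~91% of the
AGC variance, and the three vegetation classes are compositionally
distinct (PerMANOVA p = 0.001 at 999 permutations).

The group summary table (per vegetation class: plots, mean richness and
Fisher's α, within-class Bray–Curtis, class-unique species, share of
carbon in the top-5 species):

```r
report$table1$summary[, c("group", "n_plots", "richness_mean",
                          "fishers_alpha_mean", "bray_curtis_mean",
                          "n_unique_species", "top_k_agc_pct")]
#>      group n_plots richness_mean fishers_alpha_mean bray_curtis_mean
#> 1      low       7          17.6               4.10            0.654
#> 2 moderate      12          32.2               6.98            0.660
#> 3     high       6          39.0               8.00            0.617
#>   n_unique_species top_k_agc_pct
#> 1               37          59.4
#> 2               81          41.9
#> 3               67          41.0
```

How much plot-level richness would smaller plots have captured?

```r
subset(report$subsampling, metric == "richness_pct")
#>   area_ha       metric mean   sd median   p5  p95
#> 1    0.10 richness_pct 52.1 7.22   52.9 38.9 63.6
#> 4    0.25 richness_pct 70.5 7.18   70.6 58.8 82.4
#> 7    0.50 richness_pct 84.8 5.84   84.6 75.0 94.1
```

A 0.1-ha subplot sees about half the species of its 1-ha plot; 0.5 ha
sees about 85% (synthetic stands place stems without spatial clustering,
so these captures are optimistic relative to field data — see the
vignette). Individual estimators work standalone:

```r
sad <- sample_logseries_sad(alpha = 8, n_individuals = 10000, seed = 1)
length(sad)                      # 57 species
fishers_alpha(length(sad), 10000)
#> [1] 7.991262
rarefy_mao_tao(c(4, 2, 1), m = 2)
#> [1] 1.666667
```

`run_pipeline(..., outdir = )` writes every product as tidy CSV
(plot_summary, fig2_curves, table1_*, table2, fig3_fits,
fig4_nmds_coords, fig4_permanova, ks_tests, group_tests,
threshold_sensitivity, subsampling_summary, bray_curtis_matrix) plus a
YAML manifest recording seeds and settings. A thin command-line wrapper
lives at `inst/cli/agc_pipeline.R`.

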