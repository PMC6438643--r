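#' Species richness of an abundance vector
#'
#' @param abundances Non-negative integer species counts.
#' @return Number of species with at least one individual.
#' @export
species_richness <- function(abundances) {
  if (any(abundances < 0)) stopf("abundances must be non-negative")
  sum(abundances > 0)
}

#' Fisher's alpha from richness and abundance
#'
#' Solves `S = alpha * log(1 + N / alpha)` for the unique positive root —
#' the diversity parameter of the log-series species-abundance distribution.
#' The left side is strictly increasing in alpha, so a bracketed root search
#' (bracket `[1e-6, 1e6]`, expanded if needed) converges to
#' `|S_model - S| < 1e-9`.
#'
#' @param S Observed species richness, `1 <= S < N`.
#' @param N Observed number of individuals.
#' @return Fisher's alpha (positive scalar).
#' @export
fishers_alpha <- function(S, N) {
  if (!is_count(S) && !(is_scalar_num(S) && S > 0)) stopf("`S` must be a positive count")
  if (S < 1) stopf("Fisher's alpha is undefined for S = 0")
  if (S >= N) stopf("Fisher's alpha requires S < N (log-series has fewer species than individuals)")
  f <- function(a) a * log1p(N / a) - S
  lo <- 1e-6; hi <- 1e6
  while (f(hi) < 0 && hi < 1e12) hi <- hi * 10   # pathological S close to N
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-13, maxiter = 2000)
  alpha <- r$root
  # polish with a few Newton steps to the stated tolerance
  for (i in 1:50) {
    fx <- f(alpha)
    if (abs(fx) < 1e-9) break
    d <- log1p(N / alpha) - N / (alpha + N)
    alpha <- alpha - fx / d
  }
  alpha
}

#' Individual-based rarefaction (analytic expected richness)
#'
#' Expected number of species in a uniform random subsample of `m`
#' individuals drawn without replacement from the community:
#' `E[S_m] = sum_i (1 - C(N - N_i, m) / C(N, m))`, evaluated with log-gamma
#' arithmetic for numerical stability (a binomial coefficient with `m > n`
#' counts as zero).
#'
#' @param abundances Non-negative integer species counts.
#' @param m Rarefaction depth, `1 <= m <= sum(abundances)`.
#' @return Expected richness (real, `<=` observed richness).
#' @export
rarefy_mao_tao <- function(abundances, m) {
  if (any(abundances < 0) || any(abundances != round(abundances))) {
    stopf("abundances must be non-negative integers")
  }
  ni <- abundances[abundances > 0]
  N <- sum(ni)
  if (!is_count(m) || m < 1 || m > N) stopf("`m` must satisfy 1 <= m <= N (= %d)", N)
  # lchoose(n, k) is -Inf for k > n, so the exp() term vanishes correctly
  sum(1 - exp(lchoose(N - ni, m) - lchoose(N, m)))
}

#' Diversity measures within DBH size classes
#'
#' Computes richness, Fisher's alpha and total abundance on the abundance
#' vector restricted to each half-open diameter class. Classes partition
#' `[breaks[1], Inf)`; the conventional census classes are small
#' `[5, 15)`, medium `[15, 40)` and large `[40, Inf)`. Undefined measures
#' (empty class, or `S >= N` for Fisher's alpha) are reported as `NA`, not
#' zero.
#'
#' @param inventory A [plot_inventory()] (pass a merged inventory if the
#'   large class should include an outer large-tree census).
#' @param breaks Ascending lower class edges; the last class is open above.
#' @param labels Optional class labels (default `"[lo,hi)"` strings).
#' @param exclude_unidentified Drop taxonomically unidentified stems?
#' @return Data frame: `size_class`, `richness`, `fishers_alpha`, `N`.
#' @export
diversity_by_size_class <- function(inventory, breaks = c(5, 15, 40),
                                    labels = NULL,
                                    exclude_unidentified = TRUE) {
  inv <- as_plot_inventory(inventory)
  if (is.unsorted(breaks, strictly = TRUE)) stopf("`breaks` must be strictly ascending")
  edges <- c(breaks, Inf)
  if (is.null(labels)) {
    labels <- sprintf("[%g,%g)", utils::head(edges, -1), utils::tail(edges, -1))
  }
  stems <- inv$stems
  if (exclude_unidentified) stems <- stems[stems$id_level != "unidentified", , drop = FALSE]
  out <- lapply(seq_along(labels), function(i) {
    sel <- stems$dbh_cm >= edges[i] & stems$dbh_cm < edges[i + 1]
    ab <- table(stems$species[sel])
    S <- species_richness(as.integer(ab))
    N <- sum(ab)
    fa <- if (S >= 1 && S < N) fishers_alpha(S, N) else NA_real_
    data.frame(size_class = labels[i],
               richness = if (N > 0) S else NA_integer_,
               fishers_alpha = fa, N = as.integer(N))
  })
  do.call(rbind, out)
}
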