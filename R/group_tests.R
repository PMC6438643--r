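#' Permutation Kolmogorov-Smirnov test on size-class AGC curves
#'
#' Compares how two groups of plots distribute their carbon across DBH size
#' classes. Each group is summarised by the cumulative mean AGC-share curve
#' over its plots; the statistic is `D = max |cumA - cumB|` over the common
#' bin edges. Because shares are binned, plot-averaged quantities, the
#' classical two-sample KS null distribution does not apply; significance
#' comes instead from permuting plot-to-group labels (add-one convention).
#'
#' Distributions whose bins share the origin and width but differ in upper
#' edge are aligned by zero-padding; differing origins or widths are an
#' error.
#'
#' @param group_a,group_b Lists of `size_class_distribution` objects (from
#'   [size_class_distribution()]), one per plot.
#' @param n_permutations Number of label permutations (default 9999).
#' @param seed Optional RNG seed.
#' @return List of class `ks_result`: `statistic` (D), `p_value`,
#'   `group_sizes`, `n_permutations`, `method = "ks_permutation"`.
#' @export
ks_size_class <- function(group_a, group_b, n_permutations = 9999, seed = NULL) {
  if (!length(group_a) || !length(group_b)) stopf("both groups must be non-empty")
  all_d <- c(group_a, group_b)
  shares <- align_shares(all_d)
  na <- length(group_a)
  n <- nrow(shares)
  d_stat <- function(idx_a) {
    ca <- cumsum(colMeans(shares[idx_a, , drop = FALSE]))
    cb <- cumsum(colMeans(shares[-idx_a, , drop = FALSE]))
    max(abs(ca - cb))
  }
  d_obs <- d_stat(seq_len(na))
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(b) {
      d_stat(sample.int(n, na))
    }, 0) >= d_obs - 1e-12)
  })
  structure(
    list(statistic = d_obs, p_value = (1 + exceed) / (1 + n_permutations),
         group_sizes = c(length(group_a), length(group_b)),
         n_permutations = n_permutations, method = "ks_permutation"),
    class = "ks_result"
  )
}

align_shares <- function(dists) {
  ok <- vapply(dists, function(d) inherits(d, "size_class_distribution"), TRUE)
  if (!all(ok)) stopf("inputs must be size_class_distribution objects")
  if (any(vapply(dists, function(d) isTRUE(d$undefined), TRUE))) {
    stopf("a plot has zero total AGC; its share curve is undefined")
  }
  origins <- vapply(dists, function(d) d$edges[1], 0)
  widths <- vapply(dists, function(d) d$edges[2] - d$edges[1], 0)
  if (length(unique(origins)) > 1 || length(unique(widths)) > 1) {
    stopf("mismatched size-class bins (origin or width differ)")
  }
  nb <- max(vapply(dists, function(d) length(d$share), 0L))
  t(vapply(dists, function(d) c(d$share, rep(0, nb - length(d$share))), numeric(nb)))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA: `F = MS_between / MS_within` on
#' `(a - 1, N - a)` degrees of freedom (delegated to
#' [stats::oneway.test()] with equal variances). The fully degenerate case
#' (zero between- and within-group variance) reports an undefined statistic
#' with `p = 1`.
#'
#' @param groups List of numeric vectors, >= 2 groups each with >= 2
#'   observations.
#' @return List of class `anova_result`: `statistic` (F), `df`, `p_value`,
#'   `group_sizes`, `method = "anova"`.
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  a <- length(groups); N <- length(values)
  if (stats::var(values) == 0) {
    return(structure(list(statistic = NA_real_, df = c(a - 1L, N - a),
                          p_value = 1, group_sizes = lengths(groups),
                          method = "anova"), class = "anova_result"))
  }
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  structure(
    list(statistic = unname(ft$statistic), df = unname(ft$parameter),
         p_value = unname(ft$p.value), group_sizes = lengths(groups),
         method = "anova"),
    class = "anova_result"
  )
}

#' Tukey's honestly significant difference test
#'
#' For every pair of groups, the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MS_W/2 * (1/n_i + 1/n_j))` (the
#' Tukey-Kramer form for unequal sizes) with the p-value from the
#' studentized-range distribution on `(a, N - a)` via [stats::ptukey()].
#'
#' @param groups Named (optional) list of numeric vectors, as in
#'   [one_way_anova()].
#' @return Data frame: `group_i`, `group_j`, `diff`, `q`, `p_value`.
#' @export
tukey_hsd <- function(groups) {
  check_groups(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  a <- length(groups)
  N <- sum(lengths(groups))
  means <- vapply(groups, mean, 0)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  msw <- ssw / (N - a)
  pairs <- utils::combn(a, 2)
  out <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt(msw / 2 * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
    dm <- abs(means[i] - means[j])
    q <- if (se == 0) (if (dm == 0) 0 else Inf) else dm / se
    pv <- if (q == 0) 1 else stats::ptukey(q, nmeans = a, df = N - a, lower.tail = FALSE)
    data.frame(group_i = names(groups)[i], group_j = names(groups)[j],
               diff = unname(means[j] - means[i]), q = unname(q), p_value = pv)
  })
  do.call(rbind, out)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stopf("need a list of at least two groups")
  if (any(lengths(groups) < 2)) stopf("every group needs at least two observations")
  if (any(!vapply(groups, is.numeric, TRUE))) stopf("groups must be numeric vectors")
  invisible(groups)
}
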