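#' Transform an abundance table for compositional analysis
#'
#' Applies a square-root transform (damping dominant species) and then site
#' standardisation (each plot row divided by its row total, removing
#' differences in the number of stems sampled per site), in that order.
#' All-zero rows are left as zeros and flagged with a warning.
#'
#' @param table A raw `abundance_table` from [build_abundance_table()].
#' @param sqrt Apply the square-root transform?
#' @param site_standardise Divide each row by its (post-sqrt) total?
#' @return The transformed table; `attr(, "transform_state")` records which
#'   transforms were applied. Re-transforming a non-raw table is an error.
#' @export
transform_abundance <- function(table, sqrt = TRUE, site_standardise = TRUE) {
  state <- attr(table, "transform_state") %||% "raw"
  if (state != "raw") stopf("table already transformed ('%s'); start from the raw table", state)
  out <- unclass(table)
  attr(out, "transform_state") <- NULL
  if (sqrt) out <- base::sqrt(out)
  if (site_standardise) {
    rs <- rowSums(out)
    empty <- rs == 0
    if (any(empty)) warnf("%d all-zero row(s) left unstandardised", sum(empty))
    rs[empty] <- 1
    out <- out / rs
  }
  new_state <- if (sqrt && site_standardise) "sqrt_then_site_standardised"
    else if (sqrt) "sqrt" else if (site_standardise) "site_standardised" else "raw"
  structure(out, transform_state = new_state,
            class = c("abundance_table", class(out)))
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|x - y|) / sum(x + y)` for two non-negative abundance vectors:
#' 0 for identical composition, 1 for fully disjoint support.
#'
#' @param x,y Equal-length non-negative vectors.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stopf("abundances must be non-negative")
  denom <- sum(x + y)
  if (denom == 0) stopf("Bray-Curtis is undefined for two all-zero vectors")
  sum(abs(x - y)) / denom
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param table Plots-by-species abundance matrix (raw or transformed).
#' @return A symmetric matrix with zero diagonal and the plot ids as labels.
#' @export
bray_curtis_matrix <- function(table) {
  m <- as.matrix(unclass(table))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimises Kruskal stress-1 (root of the normalised squared discrepancy
#' between configuration distances and the monotone regression of those
#' distances on the input dissimilarity ranks, ties averaged within blocks).
#' The first restart starts from the classical metric-scaling configuration;
#' remaining restarts are random. The best (lowest-stress) restart is
#' returned. The iterative engine is `vegan::monoMDS`.
#'
#' @param dist A symmetric dissimilarity matrix or `dist` object.
#' @param k Number of ordination dimensions, `1 <= k < n`.
#' @param n_restarts Number of starts (first is metric-scaling based).
#' @param max_iter Iteration cap per restart.
#' @param seed Optional RNG seed.
#' @return An `nmds_result`: `points` (n x k), `stress` (in \[0, 1\]),
#'   `n_dimensions`, `converged`, `n_restarts`, `restart_stress`.
#' @export
nmds <- function(dist, k = 2, n_restarts = 20, max_iter = 500, seed = NULL) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  if (!is_count(k) || k < 1) stopf("`k` must be a positive count")
  if (k >= n) stopf("`k` must be smaller than the number of points (%d)", n)
  with_seed(seed, {
    init <- suppressWarnings(stats::cmdscale(d, k = k))
    if (ncol(init) < k) {
      init <- cbind(init, matrix(stats::rnorm(n * (k - ncol(init)), sd = 1e-4), n))
    }
    best <- NULL
    stresses <- numeric(n_restarts)
    for (r in seq_len(n_restarts)) {
      y0 <- if (r == 1) init else matrix(stats::rnorm(n * k), n, k)
      fit <- vegan::monoMDS(d, y = y0, k = k, model = "global", maxit = max_iter)
      stresses[r] <- fit$stress
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    pts <- best$points
    rownames(pts) <- labels(d) %||% rownames(as.matrix(dist))
    structure(
      list(points = pts, stress = best$stress, n_dimensions = as.integer(k),
           converged = best$icause != 1L, n_restarts = n_restarts,
           restart_stress = stresses),
      class = "nmds_result"
    )
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points, k = %d, stress = %.4f (%s, best of %d restarts)\n",
              nrow(x$points), x$n_dimensions, x$stress,
              if (x$converged) "converged" else "not converged", x$n_restarts))
  invisible(x)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared dissimilarities
#' `SS_T = (1/N) * sum_{i<j} d_ij^2` into within-group
#' (`SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2`) and between-group parts,
#' forming `pseudo-F = ((SS_T - SS_W)/(a - 1)) / (SS_W/(N - a))`. The
#' p-value comes from uniform random permutations of the group labels with
#' the add-one convention, so it is never exactly zero.
#'
#' @param dist Symmetric dissimilarity matrix or `dist`.
#' @param groups Group label per point (>= 2 groups, labels cover all
#'   points).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Optional RNG seed.
#' @return A `permanova_result`: `pseudo_F`, `df_between`, `df_within`,
#'   `p_value`, `n_permutations`, `ss_total`, `ss_within`. A fully
#'   degenerate matrix (all distances zero) yields `pseudo_F = NA` and
#'   `p_value = 1`.
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = NULL) {
  d2 <- as.matrix(dist)^2
  N <- nrow(d2)
  groups <- as.factor(groups)
  if (length(groups) != N) stopf("`groups` must label every point")
  if (any(table(groups) == 0)) groups <- droplevels(groups)
  a <- nlevels(groups)
  if (a < 2) stopf("need at least two groups")
  if (N - a <= 0) stopf("no residual degrees of freedom (N = a)")
  ss_total <- sum(d2) / (2 * N)
  ss_within_fun <- function(g) {
    s <- 0
    for (lv in levels(g)) {
      idx <- which(g == lv)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_w <- ss_within_fun(groups)
  if (ss_total <= 1e-12) {
    return(structure(list(pseudo_F = NA_real_, df_between = a - 1L,
                          df_within = N - a, p_value = 1,
                          n_permutations = n_permutations,
                          ss_total = ss_total, ss_within = ss_w),
                     class = "permanova_result"))
  }
  fstat <- function(ssw) ((ss_total - ssw) / (a - 1)) / (ssw / (N - a))
  f_obs <- fstat(ss_w)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(b) {
      fstat(ss_within_fun(groups[sample.int(N)]))
    }, 0) >= f_obs - 1e-12)
  })
  structure(
    list(pseudo_F = f_obs, df_between = a - 1L, df_within = N - a,
         p_value = (1 + exceed) / (1 + n_permutations),
         n_permutations = n_permutations,
         ss_total = ss_total, ss_within = ss_w),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PerMANOVA: pseudo-F(%d, %d) = %.3f, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}

#' Within-group dissimilarity summaries
#'
#' Mean and sample SD of the pairwise dissimilarities among plots of each
#' group — the usual "average Bray-Curtis (+/- SD)" table entry. Groups
#' with fewer than two members get `NA`.
#'
#' @param dist Symmetric dissimilarity matrix or `dist`.
#' @param groups Group label per plot.
#' @return Data frame: `group`, `n_plots`, `n_pairs`, `mean`, `sd`.
#' @export
group_dissimilarity_summary <- function(dist, groups) {
  m <- as.matrix(dist)
  groups <- as.factor(groups)
  if (length(groups) != nrow(m)) stopf("`groups` must label every plot")
  out <- lapply(levels(groups), function(lv) {
    idx <- which(groups == lv)
    vals <- m[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
    data.frame(group = lv, n_plots = length(idx), n_pairs = length(vals),
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) > 1) stats::sd(vals) else NA_real_)
  })
  do.call(rbind, out)
}

#' Species unique to a single group of plots
#'
#' A species is unique to a group when every one of its occurrences falls in
#' plots of that group; species present in two or more groups count for
#' none.
#'
#' @param table A raw `abundance_table` (plots x species).
#' @param groups Group label per plot (row).
#' @return Named integer vector: per-group count of unique species.
#' @export
unique_species <- function(table, groups) {
  state <- attr(table, "transform_state") %||% "raw"
  if (state != "raw") stopf("unique-species counts need the raw abundance table")
  m <- unclass(table)
  groups <- as.factor(groups)
  if (length(groups) != nrow(m)) stopf("`groups` must label every plot")
  lvls <- levels(droplevels(groups))
  present <- vapply(lvls, function(lv) {     # species x group occurrence
    colSums(m[groups == lv, , drop = FALSE]) > 0
  }, logical(ncol(m)))
  n_groups_per_sp <- rowSums(present)
  counts <- colSums(present & n_groups_per_sp == 1)
  stats::setNames(as.integer(counts), lvls)
}
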