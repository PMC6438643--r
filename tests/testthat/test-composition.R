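make_table <- function(m, ids = paste0("p", seq_len(nrow(m)))) {
  rownames(m) <- ids
  colnames(m) <- paste0("sp", seq_len(ncol(m)))
  structure(m, transform_state = "raw", class = c("abundance_table", class(m)))
}

test_that("square root then site standardisation, in that order", {
  tab <- make_table(rbind(c(1, 4), c(9, 0)))
  tr <- transform_abundance(tab)
  expect_equal(unname(tr[1, ]), c(1 / 3, 2 / 3))
  expect_equal(unname(tr[2, ]), c(1, 0))
  expect_equal(unname(rowSums(tr)), c(1, 1))
  expect_identical(attr(tr, "transform_state"), "sqrt_then_site_standardised")
  expect_error(transform_abundance(tr), "already transformed")
  expect_warning(transform_abundance(make_table(rbind(c(1, 1), c(0, 0)))),
                 "all-zero")
})

test_that("Bray-Curtis matches hand values and vegan", {
  expect_equal(bray_curtis(c(2, 3, 1), c(2, 3, 1)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(1, 2, 0), c(0, 2, 2)), 3 / 7)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
  set.seed(5)
  m <- matrix(rpois(60, 4), nrow = 6)
  expect_equal(unname(bray_curtis_matrix(m)[lower.tri(diag(6))]),
               as.numeric(vegan::vegdist(m, "bray")), tolerance = 1e-12)
})

test_that("site standardisation removes sampling-intensity differences", {
  set.seed(6)
  tab <- make_table(matrix(rpois(40, 5), nrow = 4))
  scaled <- unclass(tab)
  scaled[2, ] <- scaled[2, ] * 7                    # same composition, more stems
  d1 <- bray_curtis_matrix(transform_abundance(tab, sqrt = FALSE))
  d2 <- bray_curtis_matrix(transform_abundance(make_table(scaled), sqrt = FALSE))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("NMDS embeds exactly embeddable configurations with near-zero stress", {
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  o <- nmds(d3, k = 1, n_restarts = 5, seed = 1)
  expect_lt(o$stress, 1e-3)
  set.seed(2)
  pts <- matrix(rnorm(20), 10, 2)
  o2 <- nmds(as.matrix(dist(pts)), k = 2, n_restarts = 10, seed = 3)
  expect_lt(o2$stress, 0.01)
  expect_identical(nrow(o2$points), 10L)
  expect_identical(o2$n_dimensions, 2L)
  # generous dimensionality always embeds a metric matrix well
  dd <- as.matrix(dist(matrix(rnorm(21), 7, 3)))
  expect_lt(nmds(dd, k = 6, n_restarts = 5, seed = 4)$stress, 0.05)
  expect_error(nmds(d3, k = 3), "smaller")
  # determinism and best-of-restarts contract
  oa <- nmds(as.matrix(dist(pts)), k = 2, n_restarts = 6, seed = 9)
  ob <- nmds(as.matrix(dist(pts)), k = 2, n_restarts = 6, seed = 9)
  expect_identical(oa$points, ob$points)
  expect_equal(oa$stress, min(oa$restart_stress))
})

test_that("PerMANOVA matches the exhaustive permutation oracle", {
  x <- c(0, 0.1, 10, 10.1)
  d <- as.matrix(dist(x))
  groups <- c("a", "a", "b", "b")
  res <- permanova(d, groups, n_permutations = 2999, seed = 1)
  # exhaustive oracle: all 4!/(2!2!) = 6 distinct assignments
  combos <- utils::combn(4, 2)
  d2 <- d^2
  fstat <- function(ia) {
    ib <- setdiff(1:4, ia)
    ssw <- sum(d2[ia, ia]) / 4 + sum(d2[ib, ib]) / 4
    sst <- sum(d2) / 8
    ((sst - ssw) / 1) / (ssw / 2)
  }
  fs <- apply(combos, 2, fstat)
  p_exact <- mean(fs >= fstat(c(1, 2)) - 1e-12)
  expect_equal(p_exact, 1 / 3)
  se <- sqrt(p_exact * (1 - p_exact) / 2999)
  expect_lt(abs(res$p_value - p_exact), 2 * se + 1 / 2999)
  expect_identical(res$df_between, 1L)
  expect_identical(res$df_within, 2L)
})

test_that("PerMANOVA pseudo-F agrees with vegan::adonis2 and is order-invariant", {
  set.seed(13)
  m <- matrix(rpois(8 * 12, 4), nrow = 8)
  d <- vegan::vegdist(m, "bray")
  g <- rep(c("a", "b"), each = 4)
  mine <- permanova(as.matrix(d), g, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  perm <- sample(8)
  mine2 <- permanova(as.matrix(d)[perm, perm], g[perm],
                     n_permutations = 99, seed = 1)
  expect_equal(mine2$pseudo_F, mine$pseudo_F, tolerance = 1e-10)
  # degenerate: identical points
  z <- matrix(0, 4, 4)
  degen <- permanova(z, c("a", "a", "b", "b"), n_permutations = 99, seed = 1)
  expect_true(is.na(degen$pseudo_F))
  expect_equal(degen$p_value, 1)
  expect_error(permanova(z, c("a", "a", "a", "a")), "two groups")
})

test_that("group dissimilarity summaries give mean and sample SD of pairs", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.2
  d[1, 3] <- d[3, 1] <- 0.4
  d[2, 3] <- d[3, 2] <- 0.6
  g <- group_dissimilarity_summary(d, rep("x", 3))
  expect_equal(g$mean, 0.4)
  expect_equal(g$sd, 0.2)
  # identical plots give 0/0; singleton groups are undefined
  g2 <- group_dissimilarity_summary(matrix(0, 2, 2), c("x", "x"))
  expect_equal(g2$mean, 0)
  g3 <- group_dissimilarity_summary(d, c("x", "x", "y"))
  expect_true(is.na(g3$mean[g3$group == "y"]))
})

test_that("unique species are those confined to a single group", {
  tab <- make_table(rbind(c(3, 1, 0, 0),
                          c(2, 0, 0, 0),
                          c(0, 1, 4, 0),
                          c(0, 0, 1, 2)))
  u <- unique_species(tab, c("g1", "g1", "g2", "g2"))
  # sp1 only g1; sp2 both; sp3, sp4 only g2
  expect_identical(u, c(g1 = 1L, g2 = 2L))
  expect_lte(sum(u), ncol(tab))
  u2 <- unique_species(tab, c("g1", "g1", "g2", "g3"))
  expect_identical(sum(u2), 2L)                    # only sp1 and sp4 confined
  expect_error(unique_species(transform_abundance(tab), c("a", "a", "b", "b")),
               "raw")
})
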