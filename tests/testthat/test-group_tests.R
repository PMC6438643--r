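test_that("one-way ANOVA matches hand computation and classical identities", {
  r <- one_way_anova(list(c(0, 1), c(10, 11)))
  expect_equal(r$statistic, 200)                      # SSB = 100, MSW = 0.5
  expect_equal(r$df, c(1, 2))
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # location invariance
  set.seed(14)
  g <- list(rnorm(6), rnorm(5, 1), rnorm(7, 2))
  expect_equal(one_way_anova(g)$statistic,
               one_way_anova(lapply(g, `+`, 100))$statistic, tolerance = 1e-9)
  # two groups: F equals the squared pooled-variance t statistic
  a <- rnorm(8); b <- rnorm(9, 0.5)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(one_way_anova(list(a, b))$statistic,
               unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(one_way_anova(list(a, b))$p_value, tt$p.value, tolerance = 1e-10)
  # fully degenerate data
  degen <- one_way_anova(list(c(2, 2), c(2, 2)))
  expect_true(is.na(degen$statistic))
  expect_equal(degen$p_value, 1)
  expect_error(one_way_anova(list(1:3)), "two groups")
  expect_error(one_way_anova(list(1:3, 5)), "at least two observations")
})

test_that("Tukey HSD agrees with stats::TukeyHSD and is scale-invariant", {
  set.seed(15)
  groups <- list(g1 = rnorm(6, 0), g2 = rnorm(6, 1), g3 = rnorm(6, 3))
  mine <- tukey_hsd(groups)
  df <- data.frame(v = unlist(groups),
                   g = factor(rep(names(groups), each = 6)))
  ref <- stats::TukeyHSD(stats::aov(v ~ g, df))$g
  expect_equal(mine$p_value, unname(ref[, "p adj"]), tolerance = 1e-8)
  expect_equal(mine$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  # q is invariant to a common rescaling
  scaled <- tukey_hsd(lapply(groups, `*`, 13))
  expect_equal(scaled$q, mine$q, tolerance = 1e-10)
  # hand computation for the extreme pair
  means <- vapply(groups, mean, 0)
  msw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) / (18 - 3)
  q13 <- abs(means[1] - means[3]) / sqrt(msw / 2 * (1 / 6 + 1 / 6))
  expect_equal(mine$q[mine$group_i == "g1" & mine$group_j == "g3"],
               unname(q13), tolerance = 1e-10)
  ident <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$q, 0)
  expect_equal(ident$p_value, 1)
})

test_that("KS permutation test separates and equates size-class curves", {
  m <- toy_model(a = 2, b = 1, cf = 0.5)
  small_plots <- lapply(1:3, function(i) {
    size_class_distribution(make_inventory(rep(6 + i / 10, 5)), m, max_edge = 50)
  })
  big_plots <- lapply(1:3, function(i) {
    size_class_distribution(make_inventory(rep(41 + i / 10, 5)), m, max_edge = 50)
  })
  sep <- ks_size_class(small_plots, big_plots, n_permutations = 499, seed = 1)
  expect_equal(sep$statistic, 1)
  expect_lt(sep$p_value, 0.2)                          # P(relabel reproduces D=1) = 2/20
  same <- ks_size_class(small_plots, small_plots, n_permutations = 199, seed = 2)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # mismatched bins
  off <- size_class_distribution(make_inventory(c(8, 9)), m, origin = 6)
  expect_error(ks_size_class(small_plots, list(off), n_permutations = 19),
               "mismatched")
})

test_that("KS Monte-Carlo p matches exhaustive label enumeration (3 vs 3)", {
  m <- toy_model(a = 2, b = 1.8, cf = 0.5)
  set.seed(16)
  plots <- lapply(1:6, function(i) {
    size_class_distribution(random_inventory(40, seed = 100 + i), m,
                            max_edge = 80)
  })
  obs <- ks_size_class(plots[1:3], plots[4:6], n_permutations = 4999, seed = 3)
  # exhaustive oracle over all C(6,3) = 20 assignments
  shares <- t(vapply(plots, function(d) {
    c(d$share, rep(0, 15 - length(d$share)))
  }, numeric(15)))
  dstat <- function(ia) {
    max(abs(cumsum(colMeans(shares[ia, , drop = FALSE])) -
            cumsum(colMeans(shares[-ia, , drop = FALSE]))))
  }
  ds <- apply(utils::combn(6, 3), 2, dstat)
  p_exact <- mean(ds >= dstat(1:3) - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 4999)
  expect_lt(abs(obs$p_value - p_exact), 2 * se + 1 / 4999)
})
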