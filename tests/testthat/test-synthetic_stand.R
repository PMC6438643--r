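test_that("log-series SAD draws sum exactly to N over a parameter grid", {
  for (alpha in c(0.5, 4, 25)) {
    for (n in c(1, 7, 120, 5000)) {
      sad <- sample_logseries_sad(alpha, n, seed = 100 + n)
      expect_identical(sum(sad), as.integer(n))
      expect_true(all(sad >= 1))
      expect_false(is.unsorted(rev(sad)))                 # decreasing
      expect_identical(names(sad), paste0("s", seq_along(sad)))
    }
  }
  expect_identical(sample_logseries_sad(5, 1, seed = 1),
                   c(s1 = 1L))
  expect_error(sample_logseries_sad(0, 10), "alpha")
  expect_error(sample_logseries_sad(5, 0), "n_individuals")
})

test_that("same seed gives an identical SAD; the estimator closes the loop", {
  expect_identical(sample_logseries_sad(7, 500, seed = 11),
                   sample_logseries_sad(7, 500, seed = 11))
  re <- vapply(1:50, function(i) {
    sad <- sample_logseries_sad(8, 10000, seed = i)
    fishers_alpha(length(sad), 10000)
  }, 0)
  expect_lt(abs(mean(re) - 8) / 8, 0.10)
})

test_that("generated stands respect geometry, truncation and determinism", {
  cfg <- stand_config(target_density_per_ha = 400, min_dbh_cm = 5,
                      outer_extent_m = c(300, 300))
  s1 <- generate_stand(cfg, seed = 42)
  s2 <- generate_stand(cfg, seed = 42)
  expect_identical(s1$inner$stems, s2$inner$stems)
  expect_identical(s1$outer$stems, s2$outer$stems)
  st <- s1$inner$stems
  expect_true(all(st$x_m >= 0 & st$x_m < 100))
  expect_true(all(st$y_m >= 0 & st$y_m < 100))
  expect_true(min(st$dbh_cm) >= 5)
  # outer annulus: only large stems, never inside the centred inner window
  ot <- s1$outer$stems
  expect_true(all(ot$dbh_cm >= 40))
  inside <- ot$x_m >= 100 & ot$x_m < 200 & ot$y_m >= 100 & ot$y_m < 200
  expect_false(any(inside))
  # ground truth is self-consistent
  expect_identical(sum(s1$truth$true_species_totals), nrow(st))
  expect_equal(s1$truth$true_agc_tc_per_ha,
               plot_agc_density(s1$inner, default_allometry()))
})

test_that("realised stem counts match the target density within Poisson error", {
  cfg <- stand_config(target_density_per_ha = 100, species_pool_size = 20,
                      sad_alpha = 3)
  counts <- vapply(1:200, function(i) {
    nrow(generate_stand(cfg, seed = i)$inner$stems)
  }, 0)
  expect_gt(mean(counts), 80)
  expect_lt(mean(counts), 120)
})

test_that("thomas clustering aggregates stems (Clark-Evans index < 1)", {
  cfg <- stand_config(
    target_density_per_ha = 400,
    clustering = list(type = "thomas", parent_intensity_per_ha = 8,
                      mean_offspring = 50, sigma_m = 5))
  st <- generate_stand(cfg, seed = 7)$inner$stems
  n <- nrow(st)
  d <- as.matrix(dist(cbind(st$x_m, st$y_m)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)                     # brute-force nearest neighbour
  ce <- mean(nn) / (0.5 / sqrt(n / (100 * 100)))
  expect_lt(ce, 1)
})

test_that("network generation honours plot counts, labels and pool overlap", {
  net <- generate_network(tiny_network_config(), seed = 5)
  expect_length(net$stands, 6)
  expect_identical(as.integer(table(net$groups)[c("a", "b")]), c(3L, 3L))
  expect_identical(anyDuplicated(names(net$stands)), 0L)
  net25 <- generate_network(default_network_config(), seed = 1)
  expect_length(net25$stands, 25)
  # disjoint pools share nothing
  net0 <- generate_network(tiny_network_config(pool_overlap = 0), seed = 5)
  ab <- build_abundance_table(net0)
  spA <- colnames(ab)[colSums(unclass(ab)[net0$groups == "a", ]) > 0]
  spB <- colnames(ab)[colSums(unclass(ab)[net0$groups == "b", ]) > 0]
  expect_length(intersect(spA, spB), 0)
})

test_that("full pool overlap with a shared SAD equalises within- and between-class dissimilarity", {
  cfg <- stand_config(target_density_per_ha = 300, species_pool_size = 50,
                      sad_alpha = 5, pool_overlap = 1)
  classes <- list(a = list(config = cfg, n_plots = 8),
                  b = list(config = cfg, n_plots = 8))
  net <- generate_network(classes, seed = 21)
  bc <- bray_curtis_matrix(transform_abundance(build_abundance_table(net)))
  within_a <- net$groups == "a"
  w <- c(bc[within_a, within_a][upper.tri(diag(8))],
         bc[!within_a, !within_a][upper.tri(diag(8))])
  b <- as.vector(bc[within_a, !within_a])
  expect_lt(abs(mean(w) - mean(b)), 0.05)
})

test_that("stand config validation rejects inconsistent settings", {
  expect_error(stand_config(outer_extent_m = c(50, 50)), "contain")
  expect_error(stand_config(sad_alpha = -1), "sad_alpha")
  expect_error(stand_config(pool_overlap = 1.5), "pool_overlap")
  expect_error(stand_config(dbh_distribution = list(family = "gamma")), "family")
  expect_warning(generate_stand(stand_config(target_density_per_ha = 0.01), seed = 1),
                 "empty")
})

test_that("stand configs round-trip through YAML", {
  cfg <- stand_config(target_density_per_ha = 450, sad_alpha = 6,
                      dbh_distribution = list(family = "weibull",
                                              shape = 0.8, scale = 4))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], path)
  cfg2 <- read_stand_config(path)
  expect_equal(cfg2$target_density_per_ha, 450)
  expect_equal(cfg2$dbh_distribution$shape, 0.8)
  expect_identical(generate_stand(cfg, seed = 3)$inner$stems,
                   generate_stand(cfg2, seed = 3)$inner$stems)
})
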