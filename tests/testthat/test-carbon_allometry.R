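test_that("stem carbon follows the power law", {
  m <- allometry_model(a = 0.1, b = 2.5, carbon_fraction = 0.47)
  expect_equal(stem_agc(10, m), 0.47 * 0.1 * 10^2.5)   # 14.862 kg C
  expect_equal(stem_agc(0, m), 0)
  m2 <- allometry_model(a = 0.2, b = 2.5, carbon_fraction = 0.47)
  expect_equal(stem_agc(7.3, m2), 2 * stem_agc(7.3, m))  # linear in a
  expect_error(stem_agc(-1, m), "non-negative")
  expect_error(allometry_model(a = -1, b = 2), "positive")
  expect_error(allometry_model(a = 1, b = 2, carbon_fraction = 1.2), "between")
})

test_that("plot AGC density converts and scales by area", {
  # one stem holding exactly 1000 kg C: 0.5 * 1 * dbh = 1000 at dbh = 2000...
  # use a = 2, b = 1, cf = 0.5 so AGC = dbh; one 1000-"cm" stem is artificial,
  # so instead check against a hand sum on plausible stems
  m <- toy_model(a = 2, b = 1, cf = 0.5)               # AGC (kg) = dbh
  inv <- make_inventory(c(6, 12, 37))
  expect_equal(plot_agc_density(inv, m), (6 + 12 + 37) / 1000)
  empty <- make_inventory(numeric(0))
  expect_equal(plot_agc_density(empty, m), 0)
  big <- make_inventory(c(6, 12, 37), extent = c(300, 300))
  expect_equal(plot_agc_density(big, m), plot_agc_density(inv, m) / 9)
})

test_that("size-class shares match hand computation and sum to one", {
  m <- toy_model(a = 2, b = 2, cf = 0.5)               # AGC = dbh^2
  inv <- make_inventory(c(6, 12, 37))
  d <- size_class_distribution(inv, m)
  tot <- 36 + 144 + 1369
  expect_equal(d$share[1], 36 / tot, tolerance = 1e-12)   # [5,10)
  expect_equal(d$share[2], 144 / tot, tolerance = 1e-12)  # [10,15)
  expect_equal(d$share[7], 1369 / tot, tolerance = 1e-12) # [35,40)
  expect_equal(sum(d$share), 1, tolerance = 1e-9)
  expect_identical(sum(d$counts), 3L)
  # conservation against the stem-level total
  expect_equal(sum(d$agc_kg), sum(stem_agc(inv$stems$dbh_cm, m)),
               tolerance = 1e-9)
  # boundary stems land in the upper class (half-open bins)
  d15 <- size_class_distribution(make_inventory(c(15)), m)
  expect_identical(d15$counts, c(0L, 0L, 1L))             # [15,20)
})

test_that("hyperdominance finds the smallest set holding half the total", {
  expect_identical(hyperdominance(rep(2, 100))$n50, 50L)
  h <- hyperdominance(c(5, 4, 3, 2, 1))
  expect_identical(h$n50, 2L)                             # 5+4 = 9 >= 7.5
  expect_equal(h$fraction, 2 / 5)
  expect_identical(hyperdominance(c(3, 0, 2, 0, 1), quantile = 1)$n50, 3L)
  expect_error(hyperdominance(c(0, 0)), "zero")
  # brute-force scan oracle on random instances
  set.seed(77)
  for (rep in 1:20) {
    v <- rexp(sample(3:1000, 1))^2
    q <- runif(1, 0.2, 0.9)
    sorted <- sort(v, decreasing = TRUE)
    brute <- min(which(cumsum(sorted) / sum(sorted) >= q - 1e-12))
    expect_identical(hyperdominance(v, quantile = q)$n50, as.integer(brute))
  }
})

test_that("DBH-threshold sensitivity matches hand values and size-class totals", {
  m <- toy_model(a = 2, b = 1, cf = 0.5)               # AGC = dbh
  inv <- make_inventory(c(6, 12, 50))
  res <- suppressWarnings(dbh_threshold_sensitivity(inv, m, c(5, 10, 60)))
  expect_equal(res$agc_fraction, c(1, 62 / 68, 0))
  expect_equal(res$stem_fraction, c(1, 2 / 3, 0))
  expect_true(all(diff(res$agc_fraction) <= 0))
  expect_true(all(diff(res$stem_fraction) <= 0))
  # consistency: retained fraction = 1 - share of stems below the threshold
  set.seed(19)
  inv2 <- random_inventory(150)
  d <- size_class_distribution(inv2, m)
  thr <- 25
  below <- sum(d$agc_kg[d$edges[-length(d$edges)] < thr])
  expect_equal(dbh_threshold_sensitivity(inv2, m, thr)$agc_fraction,
               1 - below / sum(d$agc_kg), tolerance = 1e-9)
  expect_warning(dbh_threshold_sensitivity(inv, m, 4), "minimum")
})

test_that("species dominance rankings and top-k shares", {
  m <- toy_model(a = 2, b = 1, cf = 0.5)               # AGC = dbh
  inv <- make_inventory(c(50, 30, 20), species = c("A", "B", "C"))
  dom <- species_dominance_table(inv, m, top_k = 2)
  expect_identical(dom$by_agc$species[1:2], c("A", "B"))
  expect_equal(dom$top_k_agc_pct, 80)
  single <- species_dominance_table(make_inventory(c(10, 12), species = c("A", "A")),
                                    m, top_k = 5)
  expect_equal(single$top_k_agc_pct, 100)
  expect_equal(single$top_k_abundance_pct, 100)
  shuffled <- inv
  shuffled$stems <- inv$stems[c(3, 1, 2), ]
  dom2 <- species_dominance_table(shuffled, m, top_k = 2)
  expect_identical(dom2$by_agc$species, dom$by_agc$species)
})

test_that("vegetation classes use half-open AGC intervals", {
  cls <- assign_vegetation_class(c(2, 24, 54))
  expect_identical(as.character(cls), c("low", "moderate", "high"))
  expect_identical(as.character(assign_vegetation_class(10)), "moderate")
  expect_identical(as.character(assign_vegetation_class(40)), "high")
  four <- assign_vegetation_class(c(5, 20, 30, 50), breakpoints = c(10, 25, 45))
  expect_identical(as.character(four), paste0("class", 1:4))
  expect_error(assign_vegetation_class(-1), "non-negative")
  expect_error(assign_vegetation_class(5, breakpoints = c(40, 10)), "ascending")
})
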