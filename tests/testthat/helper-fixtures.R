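# Shared fixtures: tiny inventories built in code.

# Toy allometry with easily hand-checked numbers; carbon fraction 0.5 so
# AGC = 0.5 * a * dbh^b.
toy_model <- function(a = 1, b = 1, cf = 0.5) allometry_model(a, b, cf, "toy")

# Inventory with given DBHs (and optional species/coords) on a 1-ha plot.
make_inventory <- function(dbh, species = sprintf("sp%d", seq_along(dbh)),
                           x = NULL, y = NULL, plot_id = "p1",
                           extent = c(100, 100), min_dbh = 5,
                           id_level = rep("species", length(dbh)),
                           group = NULL) {
  n <- length(dbh)
  if (is.null(x)) x <- seq(5, 95, length.out = max(n, 2))[seq_len(n)]
  if (is.null(y)) y <- rev(seq(5, 95, length.out = max(n, 2)))[seq_len(n)]
  plot_inventory(plot_id,
                 data.frame(stem_id = sprintf("%s_%d", plot_id, seq_len(n)),
                            x_m = x, y_m = y, dbh_cm = dbh,
                            species = species, id_level = id_level),
                 extent_m = extent, min_dbh_cm = min_dbh, group = group)
}

# Uniform-random inventory for property tests.
random_inventory <- function(n, n_species = 8, plot_id = "p1", seed = NULL,
                             extent = c(100, 100)) {
  if (!is.null(seed)) set.seed(seed)
  make_inventory(dbh = 5 + rexp(n, 1 / 6),
                 species = sample(paste0("sp", seq_len(n_species)), n, replace = TRUE),
                 x = runif(n, 0, extent[1]), y = runif(n, 0, extent[2]),
                 plot_id = plot_id, extent = extent)
}

# Small two-class synthetic network for pipeline-level tests.
tiny_network_config <- function(pool_overlap = 0.25, density = c(200, 500),
                                n_plots = c(3, 3)) {
  list(
    a = list(config = stand_config(
      target_density_per_ha = density[1],
      dbh_distribution = list(family = "exponential", mean_excess_cm = 4),
      species_pool_size = 40, sad_alpha = 4, pool_overlap = pool_overlap),
      n_plots = n_plots[1]),
    b = list(config = stand_config(
      target_density_per_ha = density[2],
      dbh_distribution = list(family = "weibull", shape = 0.8, scale = 5),
      species_pool_size = 60, sad_alpha = 7, pool_overlap = pool_overlap),
      n_plots = n_plots[2])
  )
}
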