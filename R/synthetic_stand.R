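#' Configure a synthetic stand
#'
#' Describes one simulated inventory plot: a 1-ha style census window in
#' which every stem above `min_dbh_cm` is recorded, optionally nested
#' centrally inside a larger window (`outer_extent_m`) where only stems above
#' `outer_min_dbh_cm` are recorded — the classic nested large-tree design.
#'
#' @param extent_m Inner census window side lengths (m); default 100 x 100.
#' @param outer_extent_m Optional outer window side lengths (m), e.g.
#'   `c(300, 300)` for a 9-ha large-tree census; `NULL` disables it.
#' @param min_dbh_cm Minimum DBH recorded in the inner window (cm).
#' @param outer_min_dbh_cm Minimum DBH recorded in the outer annulus (cm);
#'   must exceed `min_dbh_cm`.
#' @param target_density_per_ha Expected stem density in the inner census.
#' @param dbh_distribution List: either
#'   `list(family = "exponential", mean_excess_cm = ...)` (DBH = min + Exp) or
#'   `list(family = "weibull", shape = ..., scale = ...)` truncated at
#'   `min_dbh_cm`.
#' @param clustering `list(type = "poisson")` for complete spatial
#'   randomness, or `list(type = "thomas", parent_intensity_per_ha = ...,
#'   mean_offspring = ..., sigma_m = ...)` for a Thomas cluster process
#'   (offspring displaced by an isotropic Gaussian, wrapped on the window).
#' @param species_pool_size Number of species available to this stand.
#' @param sad_alpha Fisher's alpha of the log-series species-abundance
#'   distribution individuals are drawn from.
#' @param pool_overlap Fraction of the species pool shared with other
#'   vegetation classes when used in [generate_network()], in \[0, 1\].
#' @param size_bias,size_bias_frac Optional species-size association: a
#'   fraction `size_bias_frac` of the pool is biased toward large stems with
#'   weight `dbh^size_bias`. Both default to 0 (off).
#' @param rank_noise_sd Plot-level species turnover: each plot perturbs the
#'   pool's abundance ranks multiplicatively by `exp(N(0, rank_noise_sd))`
#'   before mapping abundances to species, so different plots of the same
#'   class have overlapping but locally re-ordered dominant species
#'   (beta-diversity). 0 makes every plot of a class compositionally
#'   identical in expectation.
#' @param seed Default seed used by [generate_stand()] when none is given.
#' @return A validated `stand_config`.
#' @export
stand_config <- function(extent_m = c(100, 100), outer_extent_m = NULL,
                         min_dbh_cm = 5, outer_min_dbh_cm = 40,
                         target_density_per_ha = 700,
                         dbh_distribution = list(family = "exponential", mean_excess_cm = 4.5),
                         clustering = list(type = "poisson"),
                         species_pool_size = 100, sad_alpha = 7,
                         pool_overlap = 0.25, size_bias = 0,
                         size_bias_frac = 0, rank_noise_sd = 1.5,
                         seed = NULL) {
  if (length(extent_m) != 2 || any(extent_m <= 0)) stopf("`extent_m` must be two positive lengths")
  if (!is.null(outer_extent_m)) {
    if (length(outer_extent_m) != 2 || any(outer_extent_m <= extent_m)) {
      stopf("`outer_extent_m` must strictly contain `extent_m`")
    }
    if (outer_min_dbh_cm <= min_dbh_cm) stopf("`outer_min_dbh_cm` must exceed `min_dbh_cm`")
  }
  if (!is_scalar_num(min_dbh_cm) || min_dbh_cm <= 0) stopf("`min_dbh_cm` must be positive")
  if (!is_scalar_num(target_density_per_ha) || target_density_per_ha <= 0) {
    stopf("`target_density_per_ha` must be positive")
  }
  if (!is_scalar_num(sad_alpha) || sad_alpha <= 0) stopf("`sad_alpha` must be positive")
  if (!is_scalar_num(pool_overlap) || pool_overlap < 0 || pool_overlap > 1) {
    stopf("`pool_overlap` must lie in [0, 1]")
  }
  if (!is_scalar_num(rank_noise_sd) || rank_noise_sd < 0) {
    stopf("`rank_noise_sd` must be non-negative")
  }
  if (!is_count(species_pool_size) || species_pool_size < 1) {
    stopf("`species_pool_size` must be a positive count")
  }
  fam <- dbh_distribution$family %||% stopf("dbh_distribution needs a `family`")
  if (!fam %in% c("exponential", "weibull")) stopf("unknown DBH family '%s'", fam)
  if (fam == "exponential" && (dbh_distribution$mean_excess_cm %||% 0) <= 0) {
    stopf("exponential DBH needs a positive `mean_excess_cm`")
  }
  if (fam == "weibull" && ((dbh_distribution$shape %||% 0) <= 0 ||
                           (dbh_distribution$scale %||% 0) <= 0)) {
    stopf("weibull DBH needs positive `shape` and `scale`")
  }
  type <- clustering$type %||% "poisson"
  if (!type %in% c("poisson", "thomas")) stopf("unknown clustering type '%s'", type)
  if (type == "thomas" && ((clustering$parent_intensity_per_ha %||% 0) <= 0 ||
                           (clustering$mean_offspring %||% 0) <= 0 ||
                           (clustering$sigma_m %||% 0) <= 0)) {
    stopf("thomas clustering needs positive parent_intensity_per_ha, mean_offspring, sigma_m")
  }
  structure(
    list(extent_m = as.numeric(extent_m),
         outer_extent_m = if (!is.null(outer_extent_m)) as.numeric(outer_extent_m),
         min_dbh_cm = min_dbh_cm, outer_min_dbh_cm = outer_min_dbh_cm,
         target_density_per_ha = target_density_per_ha,
         dbh_distribution = dbh_distribution, clustering = clustering,
         species_pool_size = as.integer(species_pool_size),
         sad_alpha = sad_alpha, pool_overlap = pool_overlap,
         size_bias = size_bias, size_bias_frac = size_bias_frac,
         rank_noise_sd = rank_noise_sd, seed = seed),
    class = "stand_config"
  )
}

#' Sample a log-series species-abundance distribution
#'
#' Builds a community of exactly `n_individuals` individuals whose
#' species-abundance distribution follows the log-series with parameter `x`
#' implied by `(alpha, n_individuals)` through the Fisher relation
#' `N = alpha x / (1 - x)`. The expected number of species in abundance
#' class `k` is `phi_k = alpha x^k / k`; classes are realised by
#' low-variance systematic rounding (a single uniform offset is shared
#' across the cumulative expected counts, so each class rounds correctly in
#' expectation while total richness stays concentrated at
#' `alpha log(1 + N/alpha)`). The residual mismatch between `sum(k * n_k)`
#' and `N` is repaired on the most abundant species, so counts sum exactly
#' to `N`.
#'
#' The systematic rounding is a deliberate variance-reduction choice: the
#' generator's job is to provide communities with recoverable ground truth,
#' so realised richness tracks its log-series expectation much more tightly
#' than a fully independent random draw would.
#'
#' @param alpha Fisher's alpha of the generating log-series, `> 0`.
#' @param n_individuals Total number of individuals, `>= 1`.
#' @param seed Optional RNG seed (the caller's RNG state is restored).
#' @return Named integer vector of species counts, sorted in decreasing
#'   abundance and labelled `s1, s2, ...`.
#' @export
sample_logseries_sad <- function(alpha, n_individuals, seed = NULL) {
  if (!is_scalar_num(alpha) || alpha <= 0) stopf("`alpha` must be positive")
  if (!is_count(n_individuals) || n_individuals < 1) stopf("`n_individuals` must be >= 1")
  n <- as.integer(n_individuals)
  with_seed(seed, {
    x <- n / (n + alpha)
    kmax <- max(16L, min(ceiling(log(1e-12) / log(x)), 2^24))
    k <- seq_len(kmax)
    phi <- alpha * exp(k * log(x) - log(k))     # expected species per class
    u <- stats::runif(1)
    n_k <- diff(floor(c(0, cumsum(phi)) + u))   # systematic rounding
    counts <- rep.int(k, n_k)
    if (!length(counts)) counts <- n            # tiny N: one species holds all
    counts <- sort(counts, decreasing = TRUE)
    delta <- n - sum(counts)                    # repair on the most abundant
    i <- 1L
    while (delta != 0L && i <= length(counts)) {
      newc <- max(1L, counts[i] + delta)
      delta <- delta - (newc - counts[i])
      counts[i] <- newc
      i <- i + 1L
    }
    if (delta < 0L) {                           # still over: drop singletons
      drop <- min(-delta, length(counts) - 1L)
      counts <- counts[seq_len(length(counts) - drop)]
      counts[1] <- counts[1] - (-delta - drop)
    }
    counts <- sort(counts[counts > 0], decreasing = TRUE)
    names(counts) <- paste0("s", seq_along(counts))
    counts
  })
}

# Truncated DBH draws per the configured family.
rdbh <- function(n, dist, min_dbh) {
  if (n == 0L) return(numeric(0))
  switch(dist$family,
    exponential = min_dbh + stats::rexp(n, rate = 1 / dist$mean_excess_cm),
    weibull = {
      p0 <- stats::pweibull(min_dbh, dist$shape, dist$scale)
      stats::qweibull(p0 + stats::runif(n) * (1 - p0), dist$shape, dist$scale)
    }
  )
}

# Stem positions in [0,Lx) x [0,Ly); Thomas offspring are wrapped on the
# torus so the realised intensity stays at the target.
rpositions <- function(n, extent, clustering) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  if (clustering$type == "poisson") {
    return(cbind(x = stats::runif(n, 0, extent[1]), y = stats::runif(n, 0, extent[2])))
  }
  area_ha <- prod(extent) / 1e4
  pts <- matrix(numeric(0), ncol = 2)
  while (nrow(pts) < n) {
    n_par <- max(1L, stats::rpois(1, clustering$parent_intensity_per_ha * area_ha))
    px <- stats::runif(n_par, 0, extent[1])
    py <- stats::runif(n_par, 0, extent[2])
    n_off <- stats::rpois(n_par, clustering$mean_offspring)
    ox <- (rep(px, n_off) + stats::rnorm(sum(n_off), 0, clustering$sigma_m)) %% extent[1]
    oy <- (rep(py, n_off) + stats::rnorm(sum(n_off), 0, clustering$sigma_m)) %% extent[2]
    pts <- rbind(pts, cbind(ox, oy))
  }
  keep <- sample.int(nrow(pts), n)
  cbind(x = pts[keep, 1], y = pts[keep, 2])
}

# Map SAD ranks onto pool labels; assign species to stems, optionally biasing
# a designated subset toward large diameters with weight dbh^size_bias.
assign_species <- function(sad, pool, dbh, config) {
  k <- length(sad)
  if (k > length(pool)) {
    pool <- c(pool, paste0(pool[1], "_x", seq_len(k - length(pool))))
  }
  labels <- pool[seq_len(k)]
  n <- length(dbh)
  out <- character(n)
  remaining <- seq_len(n)
  biased <- rep(FALSE, k)
  if (config$size_bias > 0 && config$size_bias_frac > 0) {
    biased[sample.int(k, max(1L, ceiling(config$size_bias_frac * k)))] <- TRUE
  }
  for (i in order(biased, decreasing = TRUE)) {
    take <- sad[i]
    w <- if (biased[i]) dbh[remaining]^config$size_bias else NULL
    idx <- if (length(remaining) == 1L) remaining else
      sample(remaining, take, prob = w)
    out[idx] <- labels[i]
    remaining <- setdiff(remaining, idx)
  }
  out
}

#' Generate a synthetic stand
#'
#' Simulates one plot under a [stand_config()]: stem count Poisson around the
#' target density, positions from the configured point process, DBH from the
#' truncated size distribution, and species from a log-series
#' species-abundance distribution over the stand's pool. When the config has
#' an outer window, large stems (`dbh >= outer_min_dbh_cm`) are additionally
#' simulated in the surrounding annulus; the inner window is centred within
#' the outer one, and outer records never duplicate inner stems.
#'
#' @param config A [stand_config()].
#' @param plot_id Identifier for the simulated plot.
#' @param group Optional vegetation-class label.
#' @param pool Optional ordered character vector of species labels (rank 1 =
#'   most abundant expected); defaults to `s1, s2, ...`.
#' @param model Allometry used to record the stand's true AGC density in the
#'   ground truth.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return An object of class `stand`: list with `inner` and (optionally)
#'   `outer` [plot_inventory()] objects and `truth` (list with `true_alpha`,
#'   `true_species_totals`, `true_agc_tc_per_ha`, `class_label`).
#' @export
generate_stand <- function(config, plot_id = "plot1", group = NULL,
                           pool = NULL, model = default_allometry(),
                           seed = config$seed) {
  stopifnot(inherits(config, "stand_config"))
  with_seed(seed, {
    extent <- config$extent_m
    area_ha <- prod(extent) / 1e4
    mu <- config$target_density_per_ha * area_ha
    if (mu < 0.5) warnf("expected stem count %.2g; inventory may be empty", mu)
    n <- stats::rpois(1, mu)
    xy <- rpositions(n, extent, config$clustering)
    dbh <- rdbh(n, config$dbh_distribution, config$min_dbh_cm)
    if (is.null(pool)) pool <- paste0("s", seq_len(max(config$species_pool_size, 1L)))
    if (config$rank_noise_sd > 0) {   # local re-ordering of the pool ranks
      pool <- pool[order(seq_along(pool) *
                           exp(stats::rnorm(length(pool), 0, config$rank_noise_sd)))]
    }
    species <- if (n > 0) {
      sad <- sample_logseries_sad(config$sad_alpha, n)
      assign_species(sad, pool, dbh, config)
    } else character(0)
    inner <- plot_inventory(
      plot_id,
      data.frame(stem_id = if (n) paste0(plot_id, "_", seq_len(n)) else character(0),
                 x_m = xy[, 1], y_m = xy[, 2], dbh_cm = dbh, species = species,
                 id_level = rep("species", n)),
      extent_m = extent, min_dbh_cm = config$min_dbh_cm, group = group
    )
    outer <- NULL
    if (!is.null(config$outer_extent_m)) {
      oext <- config$outer_extent_m
      offset <- (oext - extent) / 2
      ann_area <- (prod(oext) - prod(extent)) / 1e4
      n_all <- stats::rpois(1, config$target_density_per_ha * ann_area)
      odbh <- rdbh(n_all, config$dbh_distribution, config$min_dbh_cm)
      odbh <- odbh[odbh >= config$outer_min_dbh_cm]
      n_out <- length(odbh)
      ox <- numeric(0); oy <- numeric(0)
      while (length(ox) < n_out) {       # uniform on the annulus by rejection
        cx <- stats::runif(n_out, 0, oext[1]); cy <- stats::runif(n_out, 0, oext[2])
        inside <- cx >= offset[1] & cx < offset[1] + extent[1] &
                  cy >= offset[2] & cy < offset[2] + extent[2]
        ox <- c(ox, cx[!inside]); oy <- c(oy, cy[!inside])
      }
      ox <- ox[seq_len(n_out)]; oy <- oy[seq_len(n_out)]
      osp <- if (n_out > 0) {
        assign_species(sample_logseries_sad(config$sad_alpha, n_out), pool, odbh, config)
      } else character(0)
      outer <- plot_inventory(
        paste0(plot_id, "_outer"),
        data.frame(stem_id = if (n_out) paste0(plot_id, "_o", seq_len(n_out)) else character(0),
                   x_m = ox, y_m = oy, dbh_cm = odbh, species = osp,
                   id_level = rep("species", n_out)),
        extent_m = oext, min_dbh_cm = config$outer_min_dbh_cm, group = group
      )
    }
    totals <- if (n > 0) {
      tb <- table(inner$stems$species)
      stats::setNames(as.integer(tb), names(tb))
    } else integer(0)
    structure(
      list(inner = inner, outer = outer,
           truth = list(true_alpha = config$sad_alpha,
                        true_species_totals = totals,
                        true_agc_tc_per_ha = if (n > 0) plot_agc_density(inner, model) else 0,
                        class_label = group)),
      class = "stand"
    )
  })
}

#' @export
print.stand <- function(x, ...) {
  print(x$inner)
  if (!is.null(x$outer)) print(x$outer)
  invisible(x)
}

#' Generate a plot network of several vegetation classes
#'
#' Builds per-class species pools sharing a fraction `pool_overlap` of
#' species (shared species occupy the same abundance ranks in every class, so
#' full overlap with a common SAD implies identical expected composition),
#' then simulates the configured number of plots per class.
#'
#' @param class_configs Named list; each element is
#'   `list(config = stand_config(...), n_plots = k)`. Names are the class
#'   labels.
#' @param seed Master seed; per-plot seeds are derived deterministically.
#' @param model Allometry recorded in each stand's ground truth.
#' @return A `stand_network`: list with `stands` (named list of `stand`
#'   objects), `groups` (named class labels) and `pools`.
#' @export
generate_network <- function(class_configs, seed = NULL,
                             model = default_allometry()) {
  if (!length(class_configs)) stopf("need at least one class")
  if (is.null(names(class_configs)) || any(names(class_configs) == "")) {
    stopf("`class_configs` must be a named list (class labels)")
  }
  pools <- build_class_pools(class_configs)
  stands <- list()
  groups <- character(0)
  for (cls in names(class_configs)) {
    cc <- class_configs[[cls]]
    if (!is_count(cc$n_plots) || cc$n_plots < 1) stopf("class '%s' needs n_plots >= 1", cls)
    for (i in seq_len(cc$n_plots)) {
      pid <- sprintf("%s_%02d", cls, i)
      stands[[pid]] <- generate_stand(cc$config, plot_id = pid, group = cls,
                                      pool = pools[[cls]], model = model,
                                      seed = derive_seed(seed, cls, i))
      groups[pid] <- cls
    }
  }
  structure(list(stands = stands, groups = groups, pools = pools),
            class = "stand_network")
}

# Shared species occupy evenly spread ranks of every class pool, so that a
# configured fraction of each pool is common across classes.
build_class_pools <- function(class_configs) {
  classes <- names(class_configs)
  sizes <- vapply(class_configs, function(cc) cc$config$species_pool_size, 1L)
  overlaps <- vapply(class_configs, function(cc) cc$config$pool_overlap, 1)
  n_shared <- round(overlaps * sizes)
  shared <- if (max(n_shared) > 0) sprintf("shared_%03d", seq_len(max(n_shared))) else character(0)
  pools <- list()
  for (j in seq_along(classes)) {
    P <- sizes[j]; m <- n_shared[j]
    pool <- sprintf("%s_%03d", classes[j], seq_len(P))
    if (m > 0) {
      pos <- unique(round(seq(1, P, length.out = m)))
      pool[pos] <- shared[seq_along(pos)]
      uniq <- sprintf("%s_%03d", classes[j], seq_len(P - length(pos)))
      pool[-pos] <- uniq
    }
    pools[[classes[j]]] <- pool
  }
  pools
}

#' Default synthetic network emulating a 25-plot dry-woodland census
#'
#' Three vegetation classes spanning the observed AGC envelope
#' (roughly 2-10, 15-35 and > 40 tC/ha) with 7, 12 and 6 plots: sparse
#' low-biomass savanna (300 stems/ha, thin-tailed DBH), miombo-type savanna
#' woodland (700 stems/ha, heavy-tailed Weibull DBH) and closed
#' woodland/forest (1050 stems/ha, heavier tail reaching > 80 cm stems).
#' Class species pools (60/110/100) share a quarter of their species.
#'
#' @param n_plots Integer vector of plots per class (low, moderate, high).
#' @return A named list suitable for [generate_network()].
#' @export
default_network_config <- function(n_plots = c(low = 7, moderate = 12, high = 6)) {
  list(
    low = list(
      config = stand_config(
        outer_extent_m = c(300, 300), target_density_per_ha = 300,
        dbh_distribution = list(family = "exponential", mean_excess_cm = 4),
        species_pool_size = 60, sad_alpha = 4, pool_overlap = 0.25),
      n_plots = n_plots[["low"]]),
    moderate = list(
      config = stand_config(
        outer_extent_m = c(300, 300), target_density_per_ha = 700,
        dbh_distribution = list(family = "weibull", shape = 0.7, scale = 3.0),
        species_pool_size = 110, sad_alpha = 7, pool_overlap = 0.25),
      n_plots = n_plots[["moderate"]]),
    high = list(
      config = stand_config(
        outer_extent_m = c(300, 300), target_density_per_ha = 1050,
        dbh_distribution = list(family = "weibull", shape = 0.7, scale = 3.5),
        species_pool_size = 100, sad_alpha = 8, pool_overlap = 0.25),
      n_plots = n_plots[["high"]])
  )
}

#' Write a stand's ground truth as a sidecar CSV
#'
#' One row per species (`plot_id, species, true_count`) plus a summary row
#' (`species = ".summary"`) holding the generating alpha, the true AGC
#' density and the class label in the remaining columns.
#'
#' @param stand A `stand` from [generate_stand()].
#' @param path Output CSV path.
#' @export
write_ground_truth <- function(stand, path) {
  stopifnot(inherits(stand, "stand"))
  tr <- stand$truth
  df <- data.frame(plot_id = stand$inner$plot_id,
                   species = names(tr$true_species_totals),
                   true_count = as.integer(tr$true_species_totals),
                   true_alpha = NA_real_, true_agc_tc_per_ha = NA_real_,
                   class_label = NA_character_)
  df <- rbind(df, data.frame(plot_id = stand$inner$plot_id, species = ".summary",
                             true_count = sum(tr$true_species_totals),
                             true_alpha = tr$true_alpha,
                             true_agc_tc_per_ha = tr$true_agc_tc_per_ha,
                             class_label = tr$class_label %||% NA_character_))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a stand configuration from a YAML file
#'
#' Keys mirror the arguments of [stand_config()] exactly.
#'
#' @param path Path to a YAML config file.
#' @return A `stand_config`.
#' @export
read_stand_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(stand_config))
  extra <- setdiff(names(y), known)
  if (length(extra)) stopf("unknown config keys: %s", paste(extra, collapse = ", "))
  y$extent_m <- unlist(y$extent_m %||% c(100, 100))
  if (!is.null(y$outer_extent_m)) y$outer_extent_m <- unlist(y$outer_extent_m)
  do.call(stand_config, y)
}
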