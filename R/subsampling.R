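#' Place a square subplot uniformly at random inside a plot
#'
#' The subplot is an axis-aligned square of side `sqrt(area_ha * 1e4)` m
#' whose origin is uniform on `[0, Lx - s] x [0, Ly - s]`; the sampled
#' window is half-open, `[x0, x0 + s) x [y0, y0 + s)`. A subplot equal to
#' the full plot is forced to origin (0, 0).
#'
#' @param extent_m Plot side lengths (m).
#' @param area_ha Subplot area in hectares.
#' @param seed Optional RNG seed.
#' @return Numeric `c(x0, y0)` with attribute `side_m`.
#' @export
place_subplot <- function(extent_m, area_ha, seed = NULL) {
  s <- sqrt(area_ha * 1e4)
  if (s > min(extent_m) + 1e-9) {
    stopf("a %.2f-ha square (side %.1f m) does not fit a %g x %g m plot",
          area_ha, s, extent_m[1], extent_m[2])
  }
  with_seed(seed, {
    x0 <- stats::runif(1, 0, max(extent_m[1] - s, 0))
    y0 <- stats::runif(1, 0, max(extent_m[2] - s, 0))
    structure(c(x0 = x0, y0 = y0), side_m = s)
  })
}

#' Sample one random subplot and compare it with the full plot
#'
#' Places one square subplot, keeps the stems falling in its half-open
#' window, and expresses subplot richness and AGC density as percentages of
#' the full-plot values: `richness_pct = 100 * S_sub / S_plot` and
#' `agc_density_pct = 100 * (AGC_sub/area_sub) / (AGC_plot/area_plot)`.
#'
#' @param inventory A [plot_inventory()] (or `stand`; the inner census is
#'   used).
#' @param model An [allometry_model()].
#' @param area_ha Subplot area (ha).
#' @param seed Optional RNG seed.
#' @return A `subplot_sample` list: `plot_id`, `area_ha`, `origin`,
#'   `richness_pct`, `agc_density_pct`, `n_stems`, `species` (labels seen
#'   in the subplot).
#' @export
subsample_once <- function(inventory, model, area_ha, seed = NULL) {
  inv <- as_plot_inventory(inventory)
  stems <- inv$stems
  s_plot <- length(unique(stems$species))
  agc <- stem_agc(stems$dbh_cm, model)
  agc_plot <- sum(agc)
  if (s_plot == 0 || agc_plot <= 0) stopf("full plot has no species or no carbon")
  origin <- place_subplot(inv$extent_m, area_ha, seed = seed)
  side <- attr(origin, "side_m")
  keep <- stems$x_m >= origin[1] & stems$x_m < origin[1] + side &
          stems$y_m >= origin[2] & stems$y_m < origin[2] + side
  sp <- unique(stems$species[keep])
  structure(
    list(plot_id = inv$plot_id, area_ha = area_ha, origin = origin,
         richness_pct = 100 * length(sp) / s_plot,
         agc_density_pct = 100 * (sum(agc[keep]) / area_ha) / (agc_plot / inv$area_ha),
         n_stems = sum(keep), species = sp),
    class = "subplot_sample"
  )
}

#' Subplot-sampling simulation over a plot network
#'
#' For each subplot area, repeats `n_iterations` times: place one random
#' square subplot in every plot, record each plot's subplot richness and
#' AGC density as percentages of its full-plot values, and pool the species
#' found across all subplots to express network-level richness as a
#' percentage of the full network species total. Summaries pool the
#' per-plot percentages over all plots and iterations; percentiles use the
#' linear-interpolation convention (R quantile type 7).
#'
#' @param network A `stand_network`, or a list of [plot_inventory()] /
#'   `stand` objects.
#' @param model An [allometry_model()].
#' @param areas Subplot areas in ha (default 0.1, 0.25 and 0.5).
#' @param n_iterations Number of random placements per plot and area.
#' @param seed Master seed (one deterministic stream per area).
#' @param keep_samples Also return the per-iteration per-plot percentages?
#' @return A `subsampling_summary`: data frame with one row per area and
#'   metric (`richness_pct`, `agc_density_pct`, `network_species_pct`)
#'   holding `mean`, `sd`, `median`, `p5`, `p95`. With
#'   `keep_samples = TRUE`, the raw matrices are attached as attribute
#'   `samples`.
#' @export
run_subsampling <- function(network, model, areas = c(0.1, 0.25, 0.5),
                            n_iterations = 1000, seed = NULL,
                            keep_samples = FALSE) {
  invs <- if (inherits(network, "stand_network")) network$stands
          else if (inherits(network, c("plot_inventory", "stand"))) list(network)
          else network
  invs <- lapply(invs, as_plot_inventory)
  n_plots <- length(invs)
  species_all <- sort(unique(unlist(lapply(invs, function(p) unique(p$stems$species)))))
  s_net <- length(species_all)
  # per-plot precomputations
  prep <- lapply(invs, function(p) {
    st <- p$stems
    agc <- stem_agc(st$dbh_cm, model)
    list(x = st$x_m, y = st$y_m, extent = p$extent_m, area = p$area_ha,
         code = match(st$species, species_all), agc = agc,
         s_plot = length(unique(st$species)), agc_plot = sum(agc))
  })
  if (any(vapply(prep, function(p) p$s_plot == 0 || p$agc_plot <= 0, TRUE))) {
    stopf("every plot needs at least one species and positive AGC")
  }
  rows <- list()
  samples <- list()
  for (area in areas) {
    sides <- sqrt(area * 1e4)
    rich <- matrix(NA_real_, n_iterations, n_plots)
    dens <- matrix(NA_real_, n_iterations, n_plots)
    netp <- numeric(n_iterations)
    with_seed(derive_seed(seed, "area", area), {
      for (it in seq_len(n_iterations)) {
        seen <- logical(s_net)
        for (j in seq_len(n_plots)) {
          p <- prep[[j]]
          x0 <- stats::runif(1, 0, max(p$extent[1] - sides, 0))
          y0 <- stats::runif(1, 0, max(p$extent[2] - sides, 0))
          keep <- p$x >= x0 & p$x < x0 + sides & p$y >= y0 & p$y < y0 + sides
          codes <- unique.default(p$code[keep])
          seen[codes] <- TRUE
          rich[it, j] <- 100 * length(codes) / p$s_plot
          dens[it, j] <- 100 * (sum(p$agc[keep]) / area) / (p$agc_plot / p$area)
        }
        netp[it] <- 100 * sum(seen) / s_net
      }
    })
    qs <- function(v) {
      q <- stats::quantile(v, c(0.5, 0.05, 0.95), names = FALSE, type = 7)
      c(mean = mean(v), sd = stats::sd(v), median = q[1], p5 = q[2], p95 = q[3])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      area_ha = area,
      metric = c("richness_pct", "agc_density_pct", "network_species_pct"),
      rbind(qs(as.vector(rich)), qs(as.vector(dens)), qs(netp)))
    if (keep_samples) {
      samples[[as.character(area)]] <- list(richness_pct = rich,
                                            agc_density_pct = dens,
                                            network_species_pct = netp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("subsampling_summary", class(out))
  if (keep_samples) attr(out, "samples") <- samples
  out
}
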