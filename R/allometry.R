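#' Define a power-law DBH allometry
#'
#' Aboveground biomass (kg, oven-dry) is modelled as `a * dbh^b` with DBH in
#' cm, and converted to carbon with a fixed carbon fraction. Coefficients are
#' deliberately configuration-driven: regional inventory allometries differ,
#' and analyses should state exactly which equation they used.
#'
#' @param a,b Power-law coefficients on the biomass (kg) scale; `a > 0`.
#' @param carbon_fraction Fraction of dry biomass that is carbon, in (0, 1).
#'   0.47 is the conventional default for tropical woody biomass.
#' @param label Free-text provenance label carried into outputs.
#' @return An object of class `allometry_model`.
#' @examples
#' m <- allometry_model(a = 0.1, b = 2.5)
#' stem_agc(10, m)
#' @export
allometry_model <- function(a, b, carbon_fraction = 0.47, label = "power_law") {
  if (!is_scalar_num(a) || a <= 0) stopf("`a` must be a positive number")
  if (!is_scalar_num(b)) stopf("`b` must be a number")
  if (!is_scalar_num(carbon_fraction) || carbon_fraction <= 0 || carbon_fraction >= 1) {
    stopf("`carbon_fraction` must lie strictly between 0 and 1")
  }
  structure(
    list(form = "power_law", a = a, b = b,
         carbon_fraction = carbon_fraction, label = label),
    class = "allometry_model"
  )
}

#' Default regional miombo allometry
#'
#' A published Tanzanian miombo aboveground-biomass power law
#' (AGB kg = 0.1027 * DBH^2.4798) with the conventional 47% carbon fraction.
#' Treat this as a sensible regional default, not a site calibration; pass
#' your own [allometry_model()] when a local equation exists.
#' @return An `allometry_model`.
#' @export
default_allometry <- function() {
  allometry_model(a = 0.1027, b = 2.4798, carbon_fraction = 0.47,
                  label = "tanzania_miombo_power_law")
}

#' @export
print.allometry_model <- function(x, ...) {
  cat(sprintf("Allometry '%s': AGC (kg C) = %.4g * %.4g * dbh^%.4g\n",
              x$label, x$carbon_fraction, x$a, x$b))
  invisible(x)
}

#' Stem aboveground carbon from DBH
#'
#' @param dbh_cm Vector of stem diameters at breast height (cm), `>= 0`.
#' @param model An [allometry_model()].
#' @return Carbon mass per stem in kg C.
#' @export
stem_agc <- function(dbh_cm, model) {
  if (!inherits(model, "allometry_model")) stopf("`model` must be an allometry_model")
  if (any(!is.finite(dbh_cm)) || any(dbh_cm < 0)) stopf("`dbh_cm` must be finite and non-negative")
  model$carbon_fraction * model$a * dbh_cm^model$b
}

#' Plot-level AGC density
#'
#' Sums per-stem carbon and scales by plot area, returning tonnes of carbon
#' per hectare.
#'
#' @param inventory A [plot_inventory()].
#' @param model An [allometry_model()].
#' @return AGC density in tC/ha.
#' @export
plot_agc_density <- function(inventory, model) {
  inv <- as_plot_inventory(inventory)
  if (inv$area_ha <= 0) stopf("plot area must be positive")
  sum(stem_agc(inv$stems$dbh_cm, model)) / 1000 / inv$area_ha
}

#' AGC distribution across DBH size classes
#'
#' Bins stems into half-open diameter classes `[lo, lo + width)` starting at
#' `origin` (default 5 cm, the census minimum) and returns each class's share
#' of total plot carbon alongside stem counts.
#'
#' @param inventory A [plot_inventory()] or stem data frame.
#' @param model An [allometry_model()].
#' @param bin_width Class width in cm (default 5).
#' @param origin Lower edge of the first class (cm).
#' @param max_edge Optional common upper edge, so distributions from several
#'   plots share bins; defaults to the smallest multiple of `bin_width`
#'   above the largest stem.
#' @return A `size_class_distribution`: list with `edges` (length nbins + 1),
#'   `counts`, `agc_kg`, `share` (sums to 1 when total AGC > 0, otherwise NA
#'   with `undefined = TRUE`).
#' @export
size_class_distribution <- function(inventory, model, bin_width = 5,
                                    origin = 5, max_edge = NULL) {
  if (!is_scalar_num(bin_width) || bin_width <= 0) stopf("`bin_width` must be positive")
  inv <- as_plot_inventory(inventory)
  dbh <- inv$stems$dbh_cm
  if (length(dbh) && any(dbh < origin)) stopf("stems below the bin origin (%g cm)", origin)
  top_needed <- if (length(dbh)) origin + bin_width * max(1, ceiling((max(dbh) - origin) / bin_width + 1e-12)) else origin + bin_width
  if (max(dbh, origin) >= top_needed) top_needed <- top_needed + bin_width
  top <- max_edge %||% top_needed
  if (top < top_needed) stopf("`max_edge` (%g) does not cover the largest stem", top)
  edges <- seq(origin, top, by = bin_width)
  nbin <- length(edges) - 1L
  agc <- stem_agc(dbh, model)
  bin <- findInterval(dbh, edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = nbin)
  agc_bin <- vapply(seq_len(nbin), function(i) sum(agc[bin == i]), 0)
  total <- sum(agc_bin)
  undefined <- total <= 0
  share <- if (undefined) rep(NA_real_, nbin) else agc_bin / total
  structure(
    list(plot_id = inv$plot_id, edges = edges, counts = counts,
         agc_kg = agc_bin, share = share, total_agc_kg = total,
         undefined = undefined),
    class = "size_class_distribution"
  )
}

#' Hyperdominance curve
#'
#' Ranks entities (stems or species) by a value such as carbon or abundance
#' and finds the smallest set holding at least a given share of the total —
#' e.g. "half of all measured biomass sits in the n50 largest trees".
#'
#' @param values Non-negative entity values; at least one must be positive.
#' @param quantile Share of the total to reach (default 0.5).
#' @return A `dominance_curve`: list with the descending `values`,
#'   `cumulative_share`, `n50` (smallest k whose top-k share reaches
#'   `quantile`) and `fraction` = n50 / number of entities.
#' @export
hyperdominance <- function(values, quantile = 0.5) {
  if (!length(values) || any(!is.finite(values)) || any(values < 0)) {
    stopf("`values` must be non-negative and finite")
  }
  if (!is_scalar_num(quantile) || quantile <= 0 || quantile > 1) {
    stopf("`quantile` must be in (0, 1]")
  }
  total <- sum(values)
  if (total <= 0) stopf("all entity values are zero; dominance undefined")
  sorted <- sort(values, decreasing = TRUE)
  cs <- cumsum(sorted) / total
  n50 <- which(cs >= quantile - 1e-12)[1]
  structure(
    list(values = sorted, cumulative_share = cs, quantile = quantile,
         n50 = as.integer(n50), fraction = n50 / length(values)),
    class = "dominance_curve"
  )
}

#' Sensitivity of inventory totals to the minimum-DBH census threshold
#'
#' For each candidate threshold, the fraction of total AGC and of stems that
#' a census restricted to `dbh >= threshold` would retain. Used to ask how
#' much carbon a rapid inventory ignoring small stems still captures.
#'
#' @param inventory A [plot_inventory()].
#' @param model An [allometry_model()].
#' @param thresholds Candidate minimum diameters (cm).
#' @return Data frame with `threshold_cm`, `agc_fraction`, `stem_fraction`.
#' @export
dbh_threshold_sensitivity <- function(inventory, model, thresholds = c(5, 10, 15)) {
  inv <- as_plot_inventory(inventory)
  if (any(thresholds < inv$min_dbh_cm)) {
    warnf("thresholds below the plot minimum DBH (%g cm) retain everything by construction",
          inv$min_dbh_cm)
  }
  dbh <- inv$stems$dbh_cm
  agc <- stem_agc(dbh, model)
  tot_agc <- sum(agc)
  n <- length(dbh)
  if (n == 0L || tot_agc <= 0) stopf("empty or zero-carbon inventory")
  res <- t(vapply(thresholds, function(th) {
    keep <- dbh >= th
    c(sum(agc[keep]) / tot_agc, sum(keep) / n)
  }, c(0, 0)))
  data.frame(threshold_cm = thresholds,
             agc_fraction = res[, 1], stem_fraction = res[, 2])
}

#' Species dominance rankings by carbon and by abundance
#'
#' Aggregates AGC and stem counts by morphospecies over one or more plots and
#' ranks species both ways, reporting the cumulative percentage held by the
#' top `top_k` species under each ranking.
#'
#' @param inventories A [plot_inventory()] or list of them.
#' @param model An [allometry_model()].
#' @param top_k How many leading species the summary percentage covers.
#' @return List with `by_agc` and `by_abundance` ranked data frames
#'   (`species`, `value`, `pct`), plus `top_k`, `top_k_agc_pct`,
#'   `top_k_abundance_pct`.
#' @export
species_dominance_table <- function(inventories, model, top_k = 5) {
  stems <- network_stems(inventories)
  if (!nrow(stems)) stopf("no stems supplied")
  agc <- stem_agc(stems$dbh_cm, model)
  agc_by_sp <- sort(tapply(agc, stems$species, sum), decreasing = TRUE)
  n_by_sp <- sort(table(stems$species), decreasing = TRUE)
  k <- min(top_k, length(agc_by_sp))
  by_agc <- data.frame(species = names(agc_by_sp),
                       value = as.numeric(agc_by_sp),
                       pct = 100 * as.numeric(agc_by_sp) / sum(agc_by_sp),
                       row.names = NULL)
  by_ab <- data.frame(species = names(n_by_sp),
                      value = as.numeric(n_by_sp),
                      pct = 100 * as.numeric(n_by_sp) / sum(n_by_sp),
                      row.names = NULL)
  list(by_agc = by_agc, by_abundance = by_ab, top_k = k,
       top_k_agc_pct = sum(by_agc$pct[seq_len(k)]),
       top_k_abundance_pct = sum(by_ab$pct[seq_len(k)]))
}

#' Classify a plot by AGC density
#'
#' Half-open intervals `[0, b1), [b1, b2), ..., [bk, Inf)` over ascending
#' breakpoints. The default two breakpoints (10 and 40 tC/ha) separate
#' sparse grassy savanna, savanna woodland, and closed woodland/forest.
#'
#' @param agc_density AGC densities (tC/ha), non-negative.
#' @param breakpoints Ascending class boundaries (tC/ha).
#' @param labels Optional class labels, length `length(breakpoints) + 1`;
#'   defaults to low/moderate/high for two breakpoints.
#' @return Factor of class labels.
#' @export
assign_vegetation_class <- function(agc_density, breakpoints = c(10, 40),
                                    labels = NULL) {
  if (any(!is.finite(agc_density)) || any(agc_density < 0)) {
    stopf("AGC densities must be finite and non-negative")
  }
  if (is.unsorted(breakpoints, strictly = TRUE)) stopf("`breakpoints` must be strictly ascending")
  if (is.null(labels)) {
    labels <- if (length(breakpoints) == 2) c("low", "moderate", "high") else
      paste0("class", seq_len(length(breakpoints) + 1L))
  }
  if (length(labels) != length(breakpoints) + 1L) {
    stopf("need %d labels for %d breakpoints", length(breakpoints) + 1L, length(breakpoints))
  }
  idx <- findInterval(agc_density, breakpoints) + 1L
  factor(labels[idx], levels = labels)
}
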