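#' Pipeline configuration
#'
#' Collects every knob of the simulate-analyse-report pipeline in one
#' object. Either supply `classes` (a [generate_network()] specification) to
#' run on synthetic stands, or `stem_table` plus `registry` paths to run on
#' a field inventory.
#'
#' @param classes Named class list as produced by [default_network_config()],
#'   or `NULL` when reading field data.
#' @param stem_table,registry Optional CSV paths (see [read_stem_table()]).
#' @param allometry An [allometry_model()].
#' @param breakpoints AGC class breakpoints (tC/ha) for grouping plots.
#' @param top_k Species kept in the dominance rankings.
#' @param rarefaction_depth `"min_n"` (rarefy to the smallest plot total) or
#'   a fixed integer depth.
#' @param n_permutations Permutations for PerMANOVA and the KS test.
#' @param nmds_k,nmds_restarts NMDS dimensionality and restarts.
#' @param thresholds Minimum-DBH thresholds (cm) for the sensitivity table.
#' @param subplot_areas,n_subplot_iterations Subplot simulation settings.
#' @param seed Master seed propagated deterministically to every
#'   stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(classes = default_network_config(),
                            stem_table = NULL, registry = NULL,
                            allometry = default_allometry(),
                            breakpoints = c(10, 40), top_k = 5,
                            rarefaction_depth = "min_n",
                            n_permutations = 999,
                            nmds_k = 3, nmds_restarts = 20,
                            thresholds = c(5, 10, 15),
                            subplot_areas = c(0.1, 0.25, 0.5),
                            n_subplot_iterations = 1000,
                            seed = 1L) {
  if (is.null(classes) && (is.null(stem_table) || is.null(registry))) {
    stopf("either `classes` or both `stem_table` and `registry` must be given")
  }
  structure(
    list(classes = classes, stem_table = stem_table, registry = registry,
         allometry = allometry, breakpoints = breakpoints, top_k = top_k,
         rarefaction_depth = rarefaction_depth,
         n_permutations = n_permutations, nmds_k = nmds_k,
         nmds_restarts = nmds_restarts, thresholds = thresholds,
         subplot_areas = subplot_areas,
         n_subplot_iterations = n_subplot_iterations, seed = seed),
    class = "pipeline_config"
  )
}

# Inner inventory + outer large-tree census merged into one (coordinates are
# kept in their own frames; only species/DBH matter downstream).
merged_large_inventory <- function(stand) {
  if (!inherits(stand, "stand") || is.null(stand$outer)) return(as_plot_inventory(stand))
  inner <- stand$inner
  stems <- rbind(inner$stems, stand$outer$stems)
  stems$plot_id <- inner$plot_id
  plot_inventory(inner$plot_id, stems, extent_m = stand$outer$extent_m,
                 min_dbh_cm = inner$min_dbh_cm, group = inner$group,
                 validate = FALSE)
}

#' Run the full inventory analysis pipeline
#'
#' Simulates (or reads) a plot network and produces the standard report
#' bundle: per-plot AGC and class assignment; cumulative size-class AGC
#' curves per class; the dominance/diversity/dissimilarity summary table;
#' per-size-class diversity; biomass-diversity regressions with AICc model
#' selection; NMDS coordinates and PerMANOVA; size-class KS tests; ANOVA +
#' Tukey comparisons; the minimum-DBH sensitivity table; subplot-sampling
#' summaries; and a manifest with the seeds used. When `outdir` is given
#' every product is written as a tidy CSV.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory (created if missing).
#' @param verbose Print stage progress?
#' @return An `agc_report` list with all products, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  model <- config$allometry

  say("stage 1/8: assembling plot network")
  network <- if (!is.null(config$classes)) {
    generate_network(config$classes, seed = derive_seed(seed, "network"),
                     model = model)
  } else {
    invs <- read_stem_table(config$stem_table, config$registry)
    structure(list(stands = lapply(invs, function(p) {
      structure(list(inner = p, outer = NULL, truth = NULL), class = "stand")
    }), groups = NULL, pools = NULL), class = "stand_network")
  }
  stands <- network$stands
  plot_ids <- names(stands)

  say("stage 2/8: carbon accounting")
  agc <- vapply(stands, function(s) plot_agc_density(s, model), 0)
  density <- vapply(stands, function(s) {
    p <- as_plot_inventory(s); nrow(p$stems) / p$area_ha
  }, 0)
  class_lab <- assign_vegetation_class(agc, config$breakpoints)
  plot_summary <- data.frame(plot_id = plot_ids, agc_tc_ha = agc,
                             stems_per_ha = density,
                             agc_class = as.character(class_lab),
                             row.names = NULL)
  max_dbh <- max(vapply(stands, function(s) max(as_plot_inventory(s)$stems$dbh_cm, 5), 0))
  max_edge <- 5 + 5 * ceiling((max_dbh - 5) / 5 + 1e-9)
  scd <- lapply(stands, function(s) size_class_distribution(s, model, max_edge = max_edge))
  fig2 <- do.call(rbind, lapply(levels(class_lab), function(cl) {
    sel <- which(class_lab == cl)
    if (!length(sel)) return(NULL)
    shares <- do.call(rbind, lapply(scd[sel], function(d) d$share))
    counts <- do.call(rbind, lapply(scd[sel], function(d) d$counts))
    edges <- scd[[sel[1]]]$edges
    data.frame(agc_class = cl, bin_lo = utils::head(edges, -1),
               bin_hi = utils::tail(edges, -1),
               mean_share = colMeans(shares),
               cum_share = cumsum(colMeans(shares)),
               mean_stems = colMeans(counts))
  }))
  stem_hyper <- hyperdominance(stem_agc(network_stems(network)$dbh_cm, model))
  thr <- do.call(rbind, lapply(seq_along(stands), function(i) {
    cbind(plot_id = plot_ids[i], agc_class = as.character(class_lab[i]),
          dbh_threshold_sensitivity(stands[[i]], model, config$thresholds))
  }))

  say("stage 3/8: dominance and diversity summary")
  table1 <- make_table1(network, model, breakpoints = config$breakpoints,
                        top_k = config$top_k, groups = class_lab,
                        n_permutations = config$n_permutations,
                        seed = derive_seed(seed, "table1"))

  say("stage 4/8: size-class diversity")
  class_bounds <- c(5, 15, 40)
  class_names <- c("small", "medium", "large")
  div_sc <- do.call(rbind, lapply(seq_along(stands), function(i) {
    merged <- merged_large_inventory(stands[[i]])
    cbind(plot_id = plot_ids[i], agc_class = as.character(class_lab[i]),
          diversity_by_size_class(merged, breaks = class_bounds,
                                  labels = class_names))
  }))
  table2 <- do.call(rbind, lapply(levels(class_lab), function(cl) {
    do.call(rbind, lapply(class_names, function(sc) {
      v <- div_sc[div_sc$agc_class == cl & div_sc$size_class == sc, ]
      data.frame(agc_class = cl, size_class = sc, n_plots = nrow(v),
                 richness_mean = mean(v$richness, na.rm = TRUE),
                 richness_sd = stats::sd(v$richness, na.rm = TRUE),
                 fishers_alpha_mean = mean(v$fishers_alpha, na.rm = TRUE),
                 fishers_alpha_sd = stats::sd(v$fishers_alpha, na.rm = TRUE))
    }))
  }))

  say("stage 5/8: biomass-diversity model selection")
  ab <- build_abundance_table(network)
  richness <- apply(unclass(ab), 1, function(v) species_richness(v))
  n_per_plot <- rowSums(unclass(ab))
  depth <- if (identical(config$rarefaction_depth, "min_n")) min(n_per_plot)
           else as.integer(config$rarefaction_depth)
  rarefied <- vapply(seq_len(nrow(ab)), function(i) {
    rarefy_mao_tao(unclass(ab)[i, ], min(depth, n_per_plot[i]))
  }, 0)
  forms <- c("linear", "saturating", "quadratic", "ricker")
  fits <- lapply(forms, function(f) {
    fit_form(richness, agc, form = f, seed = derive_seed(seed, "fit", f))
  })
  names(fits) <- forms
  selected <- select_model(fits)
  fig3 <- data.frame(
    response = "agc_tc_ha", predictor = "richness",
    form = forms,
    parameters = vapply(fits, function(f) paste(names(f$parameters),
      signif(f$parameters, 6), sep = "=", collapse = ";"), ""),
    rss = vapply(fits, function(f) f$rss, 0),
    aicc = vapply(fits, function(f) f$aicc, 0),
    r_squared = vapply(fits, function(f) f$r_squared, 0),
    converged = vapply(fits, function(f) f$converged, TRUE),
    selected = forms == selected$form)
  ols_rich <- ols_summary(richness, agc)
  ols_rare <- ols_summary(rarefied, agc)
  rho_density <- spearman_rho(density, agc)

  say("stage 6/8: composition (Bray-Curtis, NMDS, PerMANOVA)")
  trans <- transform_abundance(ab)
  bc <- bray_curtis_matrix(trans)
  ord <- nmds(bc, k = config$nmds_k, n_restarts = config$nmds_restarts,
              seed = derive_seed(seed, "nmds"))
  perm <- permanova(bc, class_lab, n_permutations = config$n_permutations,
                    seed = derive_seed(seed, "permanova"))

  say("stage 7/8: group tests")
  cls <- levels(class_lab)
  ks <- NULL
  if (length(cls) >= 2) {
    prs <- utils::combn(cls, 2)
    ks <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      ga <- scd[class_lab == prs[1, i]]
      gb <- scd[class_lab == prs[2, i]]
      if (!length(ga) || !length(gb)) return(NULL)
      r <- ks_size_class(ga, gb, n_permutations = config$n_permutations,
                         seed = derive_seed(seed, "ks", i))
      data.frame(group_a = prs[1, i], group_b = prs[2, i],
                 statistic = r$statistic, p_value = r$p_value,
                 n_permutations = r$n_permutations)
    }))
  }
  fa_plot <- vapply(seq_len(nrow(ab)), function(i) {
    S <- richness[i]; N <- n_per_plot[i]
    if (S >= 1 && S < N) fishers_alpha(S, N) else NA_real_
  }, 0)
  anova_vars <- list(agc_tc_ha = agc, stems_per_ha = density,
                     richness = richness, fishers_alpha = fa_plot)
  group_tests <- do.call(rbind, lapply(names(anova_vars), function(v) {
    vals <- split(anova_vars[[v]], class_lab)
    vals <- lapply(vals, function(x) x[is.finite(x)])
    vals <- vals[lengths(vals) >= 2]
    if (length(vals) < 2) return(NULL)
    an <- one_way_anova(vals)
    tk <- tukey_hsd(vals)
    rbind(data.frame(variable = v, comparison = "omnibus",
                     statistic = an$statistic, p_value = an$p_value,
                     method = "anova"),
          data.frame(variable = v,
                     comparison = paste(tk$group_i, tk$group_j, sep = " vs "),
                     statistic = tk$q, p_value = tk$p_value,
                     method = "tukey"))
  }))

  say("stage 8/8: subplot-sampling simulation")
  subs <- run_subsampling(network, model, areas = config$subplot_areas,
                          n_iterations = config$n_subplot_iterations,
                          seed = derive_seed(seed, "subsampling"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("miomboAGC")),
    r_version = R.version.string,
    seed = seed,
    allometry = list(label = model$label, a = model$a, b = model$b,
                     carbon_fraction = model$carbon_fraction),
    breakpoints = config$breakpoints,
    n_plots = length(stands),
    rarefaction_depth = depth,
    n_permutations = config$n_permutations,
    subplot_areas = config$subplot_areas,
    n_subplot_iterations = config$n_subplot_iterations,
    nmds = list(k = config$nmds_k, restarts = config$nmds_restarts,
                stress = ord$stress, converged = ord$converged)
  )

  report <- structure(
    list(network = network, plot_summary = plot_summary, fig2_curves = fig2,
         stem_hyperdominance = stem_hyper, threshold_sensitivity = thr,
         table1 = table1, size_class_diversity = div_sc, table2 = table2,
         fits = fits, selected_form = selected$form, fig3 = fig3,
         ols_richness = ols_rich, ols_rarefied = ols_rare,
         spearman_density_agc = rho_density,
         distance_matrix = bc, nmds = ord, permanova = perm,
         ks_tests = ks, group_tests = group_tests,
         subsampling = subs, manifest = manifest),
    class = "agc_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  invisible(report)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  w(report$plot_summary, "plot_summary.csv")
  w(report$fig2_curves, "fig2_curves.csv")
  w(report$threshold_sensitivity, "threshold_sensitivity.csv")
  w(report$table1$summary, "table1_summary.csv")
  w(report$table1$dominance, "table1_dominance.csv")
  w(report$size_class_diversity, "size_class_diversity.csv")
  w(report$table2, "table2.csv")
  w(report$fig3, "fig3_fits.csv")
  coords <- data.frame(plot_id = rownames(report$nmds$points), report$nmds$points)
  names(coords)[-1] <- paste0("axis", seq_len(ncol(report$nmds$points)))
  w(coords, "fig4_nmds_coords.csv")
  w(data.frame(pseudo_F = report$permanova$pseudo_F,
               df_between = report$permanova$df_between,
               df_within = report$permanova$df_within,
               p_value = report$permanova$p_value,
               n_permutations = report$permanova$n_permutations),
    "fig4_permanova.csv")
  w(report$ks_tests, "ks_tests.csv")
  w(report$group_tests, "group_tests.csv")
  w(as.data.frame(report$subsampling), "subsampling_summary.csv")
  dm <- as.data.frame(report$distance_matrix)
  dm <- cbind(plot_id = rownames(report$distance_matrix), dm)
  w(dm, "bray_curtis_matrix.csv")
  yaml::write_yaml(report$manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' @export
print.agc_report <- function(x, ...) {
  ps <- x$plot_summary
  cat(sprintf("Inventory report: %d plots, mean AGC %.1f +/- %.1f tC/ha (range %.1f-%.1f)\n",
              nrow(ps), mean(ps$agc_tc_ha), stats::sd(ps$agc_tc_ha),
              min(ps$agc_tc_ha), max(ps$agc_tc_ha)))
  cat(sprintf("Half of stem AGC in the %d largest stems (%.1f%% of stems)\n",
              x$stem_hyperdominance$n50, 100 * x$stem_hyperdominance$fraction))
  cat(sprintf("Best biomass-diversity form: %s; richness OLS r2 = %.2f\n",
              x$selected_form, x$ols_richness$r_squared))
  cat(sprintf("NMDS stress = %.3f (k = %d); PerMANOVA p = %.4g\n",
              x$nmds$stress, x$nmds$n_dimensions, x$permanova$p_value))
  invisible(x)
}

#' Dominance / diversity / dissimilarity summary by plot group
#'
#' The classic inventory summary table: for each group of plots, the top-k
#' species by carbon and by stems with the percentage of the total they
#' hold, plot counts, mean (SD) richness and Fisher's alpha, total
#' richness, within-group Bray-Curtis mean (SD) on square-root transformed
#' and site-standardised abundances, and the number of species unique to
#' the group.
#'
#' @param network A `stand_network` or list of inventories.
#' @param model An [allometry_model()].
#' @param breakpoints AGC breakpoints used to group plots when `groups` is
#'   not supplied.
#' @param top_k Species per dominance ranking.
#' @param groups Optional explicit group label per plot.
#' @param labels Optional labels for [assign_vegetation_class()].
#' @param n_permutations,seed PerMANOVA settings for the between-group
#'   composition test attached to the summary.
#' @return List with `summary` (one row per group), `dominance` (long data
#'   frame of ranked species) and `permanova`.
#' @export
make_table1 <- function(network, model, breakpoints = c(10, 40), top_k = 5,
                        groups = NULL, labels = NULL,
                        n_permutations = 999, seed = NULL) {
  stands <- if (inherits(network, "stand_network")) network$stands else network
  invs <- lapply(stands, as_plot_inventory)
  if (is.null(groups)) {
    agc <- vapply(invs, function(p) plot_agc_density(p, model), 0)
    groups <- assign_vegetation_class(agc, breakpoints, labels = labels)
  }
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stopf("need at least two non-empty groups")
  ab <- build_abundance_table(invs)
  bc <- bray_curtis_matrix(transform_abundance(ab))
  diss <- group_dissimilarity_summary(bc, groups)
  uniq <- unique_species(ab, groups)
  perm <- permanova(bc, droplevels(groups), n_permutations = n_permutations,
                    seed = seed)
  richness <- apply(unclass(ab), 1, species_richness)
  n_per_plot <- rowSums(unclass(ab))
  fa <- vapply(seq_along(richness), function(i) {
    if (richness[i] >= 1 && richness[i] < n_per_plot[i]) {
      fishers_alpha(richness[i], n_per_plot[i])
    } else NA_real_
  }, 0)
  summary <- NULL
  dominance <- NULL
  for (lv in levels(groups)) {
    sel <- which(groups == lv)
    if (!length(sel)) next
    dom <- species_dominance_table(invs[sel], model, top_k = top_k)
    k <- dom$top_k
    dominance <- rbind(dominance,
      data.frame(group = lv, ranking = "agc", rank = seq_len(k),
                 species = dom$by_agc$species[seq_len(k)],
                 pct = dom$by_agc$pct[seq_len(k)]),
      data.frame(group = lv, ranking = "abundance", rank = seq_len(k),
                 species = dom$by_abundance$species[seq_len(k)],
                 pct = dom$by_abundance$pct[seq_len(k)]))
    grp_ab <- unclass(ab)[sel, , drop = FALSE]
    summary <- rbind(summary, data.frame(
      group = lv, n_plots = length(sel),
      richness_mean = mean(richness[sel]),
      richness_sd = stats::sd(richness[sel]),
      fishers_alpha_mean = mean(fa[sel], na.rm = TRUE),
      fishers_alpha_sd = stats::sd(fa[sel], na.rm = TRUE),
      total_richness = sum(colSums(grp_ab) > 0),
      bray_curtis_mean = diss$mean[diss$group == lv],
      bray_curtis_sd = diss$sd[diss$group == lv],
      n_unique_species = unname(uniq[lv]),
      top_k_agc_pct = dom$top_k_agc_pct,
      top_k_abundance_pct = dom$top_k_abundance_pct))
  }
  rownames(summary) <- NULL
  list(summary = summary, dominance = dominance, permanova = perm)
}
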