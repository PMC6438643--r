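#' Construct a plot inventory
#'
#' A plot inventory bundles a stem table with the plot geometry and census
#' protocol: a rectangular extent in metres with plot-local, half-open
#' coordinates (`0 <= x < extent_x`), and the minimum DBH recorded.
#'
#' @param plot_id Plot identifier.
#' @param stems Data frame with columns `stem_id`, `x_m`, `y_m`, `dbh_cm`,
#'   `species` and optionally `id_level` (one of `"species"`, `"genus"`,
#'   `"local_name"`, `"unidentified"`; default `"species"`). A `plot_id`
#'   column, if present, must match `plot_id`.
#' @param extent_m Numeric pair: plot side lengths in metres.
#' @param min_dbh_cm Minimum diameter recorded in this census (cm).
#' @param group Optional vegetation-class label for the plot.
#' @param validate Check stem invariants (coordinates inside the extent,
#'   DBH at or above the census minimum)?
#' @return An object of class `plot_inventory` with fields `plot_id`,
#'   `extent_m`, `area_ha`, `min_dbh_cm`, `group`, `stems`.
#' @export
plot_inventory <- function(plot_id, stems, extent_m = c(100, 100),
                           min_dbh_cm = 5, group = NULL, validate = TRUE) {
  if (length(extent_m) != 2 || any(!is.finite(extent_m)) || any(extent_m <= 0)) {
    stopf("`extent_m` must be two positive side lengths")
  }
  if (!is_scalar_num(min_dbh_cm) || min_dbh_cm <= 0) stopf("`min_dbh_cm` must be positive")
  stems <- as.data.frame(stems)
  needed <- c("stem_id", "x_m", "y_m", "dbh_cm", "species")
  miss <- setdiff(needed, names(stems))
  if (length(miss)) stopf("stem table missing columns: %s", paste(miss, collapse = ", "))
  if (is.null(stems$id_level)) stems$id_level <- "species"
  if (!is.null(stems$plot_id) && nrow(stems) && any(stems$plot_id != plot_id)) {
    stopf("stem rows carry a plot_id other than '%s'", plot_id)
  }
  stems$plot_id <- rep(as.character(plot_id), length.out = nrow(stems))
  stems <- stems[c("plot_id", "stem_id", "x_m", "y_m", "dbh_cm", "species", "id_level")]
  stems$species <- as.character(stems$species)
  stems$id_level <- as.character(stems$id_level)
  inv <- structure(
    list(plot_id = as.character(plot_id), extent_m = as.numeric(extent_m),
         area_ha = prod(extent_m) / 1e4, min_dbh_cm = min_dbh_cm,
         group = group, stems = stems),
    class = "plot_inventory"
  )
  if (validate) validate_inventory(inv)
  inv
}

#' @export
print.plot_inventory <- function(x, ...) {
  cat(sprintf("Plot '%s': %g x %g m (%.2f ha), min DBH %g cm, %d stems%s\n",
              x$plot_id, x$extent_m[1], x$extent_m[2], x$area_ha,
              x$min_dbh_cm, nrow(x$stems),
              if (is.null(x$group)) "" else sprintf(", group '%s'", x$group)))
  invisible(x)
}

validate_inventory <- function(inv) {
  s <- inv$stems
  bad <- which(!is.finite(s$dbh_cm) | s$dbh_cm <= 0 |
                 s$dbh_cm < inv$min_dbh_cm - 1e-9 |
                 s$x_m < 0 | s$x_m >= inv$extent_m[1] |
                 s$y_m < 0 | s$y_m >= inv$extent_m[2])
  if (length(bad)) {
    stopf("plot '%s': %d invalid stem row(s): %s",
          inv$plot_id, length(bad),
          paste(utils::head(bad, 10), collapse = ", "))
  }
  lv <- c("species", "genus", "local_name", "unidentified")
  if (nrow(s) && !all(s$id_level %in% lv)) {
    stopf("plot '%s': id_level must be one of %s", inv$plot_id, paste(lv, collapse = "/"))
  }
  invisible(inv)
}

as_plot_inventory <- function(x) {
  if (inherits(x, "plot_inventory")) return(x)
  if (inherits(x, "stand")) return(x$inner)
  stopf("expected a plot_inventory")
}

# Flatten an inventory, a stand, or a list of either into one stem table.
network_stems <- function(x) {
  if (inherits(x, c("plot_inventory", "stand"))) x <- list(x)
  if (inherits(x, "stand_network")) x <- x$stands
  do.call(rbind, lapply(x, function(p) as_plot_inventory(p)$stems))
}

#' Read and write stem tables and plot registries
#'
#' The stem-table CSV dialect is one stem per row with header columns
#' `plot_id, stem_id, x_m, y_m, dbh_cm, species, id_level` (comma separated,
#' UTF-8, decimal point). The plot registry has columns
#' `plot_id, extent_x_m, extent_y_m, min_dbh_cm, group`.
#'
#' @param path File path.
#' @param registry A registry data frame (from [read_plot_registry()]) or
#'   path to one.
#' @return `read_stem_table()` returns a named list of [plot_inventory()]
#'   objects, one per registry row with matching stems; unidentified stems
#'   are retained (flagged via `id_level`). Validation failures name the
#'   offending rows.
#' @export
read_stem_table <- function(path, registry) {
  if (is.character(registry)) registry <- read_plot_registry(registry)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("plot_id", "stem_id", "x_m", "y_m", "dbh_cm", "species", "id_level")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) stopf("stem table missing columns: %s", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(tab$plot_id), registry$plot_id)
  if (length(unknown)) stopf("stems reference unregistered plots: %s",
                             paste(unknown, collapse = ", "))
  invs <- lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    stems <- tab[tab$plot_id == r$plot_id, , drop = FALSE]
    rownames(stems) <- NULL
    plot_inventory(r$plot_id, stems,
                   extent_m = c(r$extent_x_m, r$extent_y_m),
                   min_dbh_cm = r$min_dbh_cm,
                   group = if (!is.null(r$group) && !is.na(r$group)) r$group)
  })
  names(invs) <- registry$plot_id
  invs
}

#' @rdname read_stem_table
#' @param inventories A list of [plot_inventory()] objects (or one).
#' @export
write_stem_table <- function(inventories, path) {
  utils::write.csv(network_stems(inventories), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_stem_table
#' @export
read_plot_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("plot_id", "extent_x_m", "extent_y_m", "min_dbh_cm")
  miss <- setdiff(needed, names(reg))
  if (length(miss)) stopf("plot registry missing columns: %s", paste(miss, collapse = ", "))
  reg
}

#' @rdname read_stem_table
#' @export
write_plot_registry <- function(inventories, path) {
  if (inherits(inventories, c("plot_inventory", "stand"))) inventories <- list(inventories)
  if (inherits(inventories, "stand_network")) inventories <- inventories$stands
  reg <- do.call(rbind, lapply(inventories, function(p) {
    p <- as_plot_inventory(p)
    data.frame(plot_id = p$plot_id, extent_x_m = p$extent_m[1],
               extent_y_m = p$extent_m[2], min_dbh_cm = p$min_dbh_cm,
               group = p$group %||% NA_character_)
  }))
  utils::write.csv(reg, path, row.names = FALSE)
  invisible(path)
}

#' Build a plots-by-species abundance matrix
#'
#' Counts stems per plot and morphospecies, optionally restricted to a
#' half-open DBH window `[lo, hi)` and excluding stems with no taxonomic
#' identification at all.
#'
#' @param inventories A [plot_inventory()], a `stand`, a list of either, or
#'   a `stand_network`.
#' @param dbh_range Optional `c(lo, hi)` half-open diameter window in cm
#'   (`hi` may be `Inf`).
#' @param exclude_unidentified Drop stems with `id_level == "unidentified"`
#'   (default TRUE, mirroring standard inventory practice)?
#' @return Integer matrix (plots x species) of class `abundance_table` with
#'   attribute `transform_state = "raw"`.
#' @export
build_abundance_table <- function(inventories, dbh_range = NULL,
                                  exclude_unidentified = TRUE) {
  if (inherits(inventories, c("plot_inventory", "stand"))) inventories <- list(inventories)
  if (inherits(inventories, "stand_network")) inventories <- inventories$stands
  if (!length(inventories)) stopf("need at least one inventory")
  plot_ids <- vapply(inventories, function(p) as_plot_inventory(p)$plot_id, "")
  stems <- network_stems(inventories)
  if (!is.null(dbh_range)) {
    if (length(dbh_range) != 2 || dbh_range[2] <= dbh_range[1]) {
      stopf("`dbh_range` must be an increasing pair [lo, hi)")
    }
    stems <- stems[stems$dbh_cm >= dbh_range[1] & stems$dbh_cm < dbh_range[2], , drop = FALSE]
  }
  if (exclude_unidentified) {
    stems <- stems[stems$id_level != "unidentified", , drop = FALSE]
  }
  species <- sort(unique(stems$species))
  tab <- matrix(0L, nrow = length(plot_ids), ncol = length(species),
                dimnames = list(plot_ids, species))
  if (nrow(stems)) {
    counts <- table(factor(stems$plot_id, levels = plot_ids),
                    factor(stems$species, levels = species))
    tab[] <- as.integer(counts)
  }
  structure(tab, transform_state = "raw", class = c("abundance_table", class(tab)))
}
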