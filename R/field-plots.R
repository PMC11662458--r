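# Plot-level AGB aggregation from tree records.
#
# Tree lists may contain cluster records (several identical stems recorded
# once with a count); these are expanded before summing. Plot AGB density is
# the sum of per-tree AGB over live and dead trees at or above the common
# 7.6 cm DBH minimum, divided by plot area.

#' Expand cluster records into individual trees
#'
#' A record with `cluster_count = k` becomes `k` identical records with
#' `cluster_count = 1`, each keeping the recorded average DBH and height.
#'
#' @param trees tree data frame with a `cluster_count` column (absent counts
#'   are treated as 1).
#' @return expanded tree data frame.
#' @export
expand_clusters <- function(trees) {
  if (!"cluster_count" %in% names(trees)) trees$cluster_count <- 1L
  k <- trees$cluster_count
  if (any(is.na(k)) || any(k < 1) || any(k != as.integer(k))) {
    stop("cluster_count must be a positive integer", call. = FALSE)
  }
  out <- trees[rep(seq_len(nrow(trees)), times = k), , drop = FALSE]
  out$cluster_count <- 1L
  rownames(out) <- NULL
  out
}

#' Aggregate tree records to plot AGB density
#'
#' Sums per-tree AGB (kg) over live and dead trees with DBH at or above the
#' minimum (7.6 cm, the largest common minimum across the source
#' protocols), converts to Mg and divides by plot area. Cluster records are
#' expanded first, so the result is the same whether or not the caller
#' expanded them.
#'
#' @param trees tree data frame (`dbh_cm`, `agb_kg`, optional `status`,
#'   `cluster_count`).
#' @param area_ha plot area in hectares (> 0).
#' @param dbh_min_cm inclusive DBH threshold (cm).
#' @param live_only drop dead trees (for comparisons against live-only map
#'   products); the default keeps live + dead standing AGB.
#' @return plot AGB density in Mg/ha.
#' @export
aggregate_plot_agb <- function(trees, area_ha, dbh_min_cm = 7.6,
                               live_only = FALSE) {
  if (area_ha <= 0) stop("plot area must be > 0", call. = FALSE)
  trees <- expand_clusters(trees)
  if (nrow(trees) == 0L) return(0)
  if (any(trees$agb_kg < 0)) stop("negative agb_kg", call. = FALSE)
  keep <- trees$dbh_cm >= dbh_min_cm
  if (live_only && "status" %in% names(trees)) {
    keep <- keep & trees$status == "live"
  }
  sum(trees$agb_kg[keep]) / 1000 / area_ha
}

#' Placeholder power-law allometry
#'
#' `agb_kg = a * dbh^b`, a DBH-only stand-in used for synthetic tree lists.
#' Real per-tree AGB (e.g., from the national inventory's component-ratio
#' allometry) is treated as an input elsewhere.
#'
#' @param dbh_cm diameter at breast height (cm), > 0.
#' @param a multiplier (> 0).
#' @param b exponent.
#' @return per-tree AGB in kg.
#' @export
placeholder_allometry <- function(dbh_cm, a = 0.08, b = 2.4) {
  if (any(dbh_cm <= 0)) stop("dbh must be > 0", call. = FALSE)
  if (a <= 0) stop("allometry multiplier must be > 0", call. = FALSE)
  a * dbh_cm^b
}

#' Read a tree CSV
#'
#' Expected columns: `species`, `dbh_cm`, `height_m`, `status`, `agb_kg`,
#' `cluster_count` (missing `cluster_count` defaults to 1; missing heights
#' are accepted).
#'
#' @param path CSV file path.
#' @return tree data frame.
#' @export
read_tree_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dbh_cm", "agb_kg")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("tree CSV lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"cluster_count" %in% names(tr)) tr$cluster_count <- 1L
  tr
}

#' Write a plot table to CSV
#'
#' @param plots plot data frame (`plot_id`, `x_km`, `y_km`, `area_ha`,
#'   `agb_mg_ha`, ...).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_plot_csv <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE)
  invisible(path)
}
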