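# Management-unit (MU) totals from pixel-level posterior predictive draws.
#
# Aggregation always happens per draw, never on pixel summaries: for each
# retained draw the MU mean density is the average over the MU's unmasked
# pixels and the total is that mean times the MU area. Summaries (median,
# SD, 95% interval) are then taken across draws, so the MU totals carry the
# full joint predictive uncertainty.

#' Convert megagrams to teragrams
#'
#' @param total_mg mass in Mg (>= 0).
#' @return mass in Tg (`/ 1e6`).
#' @export
mg_to_tg <- function(total_mg) {
  if (any(total_mg < 0)) stop("total mass must be >= 0", call. = FALSE)
  total_mg / 1e6
}

#' Management-unit posterior predictive estimates
#'
#' Per draw, the MU mean AGB density (Mg/ha) is the average over the MU's
#' pixels and the MU total (Mg) is density times area; medians, SDs and
#' 95% intervals are computed across draws and totals converted to Tg. The
#' relative SD (100 * SD / median) is identical for the total and the mean
#' density because both are the same draws scaled by area.
#'
#' @param agb_draws AGB-scale PPD draw matrix, draws x pixels (all pixels
#'   share the draw index).
#' @param mu factor/character of MU labels, one per pixel column.
#' @param pixel_area_ha area of one pixel (0.09 ha for 30 m cells).
#' @param area_ha optional named vector of externally supplied MU areas
#'   (ha); the default is unmasked-pixel count times `pixel_area_ha`.
#' @return data frame of class `agbgeo_areal`, one row per MU: `mu_id`,
#'   `n_pixels`, `area_ha`, mean density summaries (`mean_mg_ha`,
#'   `mean_lo`, `mean_hi`, `mean_sd`), total summaries (`total_tg`,
#'   `total_lo`, `total_hi`, `total_sd`) and `rsd_pct`.
#' @export
mu_joint_estimate <- function(agb_draws, mu, pixel_area_ha = 0.09,
                              area_ha = NULL) {
  agb_draws <- as.matrix(agb_draws)
  if (length(mu) != ncol(agb_draws)) {
    stop("one MU label per draw column is required", call. = FALSE)
  }
  ids <- unique(as.character(mu))
  rows <- lapply(ids, function(id) {
    sel <- mu == id
    if (!any(sel)) stop("empty management unit: ", id, call. = FALSE)
    dens <- rowMeans(agb_draws[, sel, drop = FALSE])
    a <- if (!is.null(area_ha)) {
      if (is.null(names(area_ha))) area_ha[match(id, ids)] else area_ha[[id]]
    } else sum(sel) * pixel_area_ha
    tot_tg <- mg_to_tg(dens * a)
    qd <- stats::quantile(dens, c(0.5, 0.025, 0.975), names = FALSE)
    qt <- stats::quantile(tot_tg, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(mu_id = id, n_pixels = sum(sel), area_ha = a,
               mean_mg_ha = qd[1], mean_lo = qd[2], mean_hi = qd[3],
               mean_sd = stats::sd(dens),
               total_tg = qt[1], total_lo = qt[2], total_hi = qt[3],
               total_sd = stats::sd(tot_tg),
               rsd_pct = 100 * stats::sd(dens) / qd[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("agbgeo_areal", "data.frame")
  out
}
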