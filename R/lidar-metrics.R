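# Canopy structure metrics from normalized point heights on a 30 m grid.
#
# Conventions, pinned so oracles match exactly: the canopy threshold is
# strictly greater than 2 m; percentiles use linear interpolation between
# order statistics (R quantile type 7); the canopy height model (CHM) for
# rumple is built at 1 m from the highest return per fine cell (empty fine
# cells count as ground, height 0) and triangulated with a fixed NW-SE
# diagonal per grid square.

PCTL_LEVELS <- c(5, 10, 20, 25, 30, 40, 50, 60, 70, 75, 80, 90, 95)
PCTL_NAMES <- paste0("p", sprintf("%02d", PCTL_LEVELS))

#' Per-cell height metrics from normalized point heights
#'
#' Canopy cover is the percent of returns above 2 m out of all returns in
#' the cell; mean, SD and the 13 height percentiles are computed over the
#' above-2 m heights only. Cells whose returns are all at or below 2 m get
#' cover 0 and undefined (NA) height metrics.
#'
#' @param z numeric vector of normalized heights (m) for the points in one
#'   cell.
#' @return one-row data frame: `canopy_cover_pct`, `mean_height_m`,
#'   `sd_height_m`, `p05`...`p95`, `n_points`.
#' @export
compute_cell_metrics <- function(z) {
  n <- length(z)
  if (n == 0L) {
    out <- as.data.frame(as.list(rep(NA_real_, 3 + length(PCTL_LEVELS))))
    names(out) <- c("canopy_cover_pct", "mean_height_m", "sd_height_m", PCTL_NAMES)
    out$n_points <- 0L
    return(out)
  }
  above <- z[z > 2]
  cover <- 100 * length(above) / n
  if (length(above) == 0L) {
    hm <- rep(NA_real_, 2 + length(PCTL_LEVELS))
  } else {
    pct <- stats::quantile(above, probs = PCTL_LEVELS / 100, names = FALSE, type = 7)
    hm <- c(mean(above), if (length(above) > 1L) stats::sd(above) else 0, pct)
  }
  out <- as.data.frame(as.list(c(cover, hm)))
  names(out) <- c("canopy_cover_pct", "mean_height_m", "sd_height_m", PCTL_NAMES)
  out$n_points <- n
  out
}

#' Canopy rumple from a canopy height model
#'
#' Ratio of the 3-D surface area of the triangulated CHM to its planimetric
#' area. Each grid square is split into two triangles along the NW-SE
#' diagonal; triangle areas come from the cross-product formula. A flat CHM
#' has rumple exactly 1; relief increases it.
#'
#' @param chm numeric matrix of canopy heights (m); rows index y, columns x.
#' @param spacing_m node spacing of the CHM (m).
#' @return surface-to-plan area ratio (>= 1).
#' @export
compute_rumple <- function(chm, spacing_m = 1) {
  if (!is.matrix(chm) || nrow(chm) < 2L || ncol(chm) < 2L) {
    stop("CHM must have at least 2 x 2 nodes", call. = FALSE)
  }
  if (!all(is.finite(chm))) stop("CHM heights must be finite", call. = FALSE)
  s <- spacing_m
  nr <- nrow(chm); nc <- ncol(chm)
  z00 <- chm[-nr, -nc]; z10 <- chm[-1, -nc]
  z01 <- chm[-nr, -1];  z11 <- chm[-1, -1]
  # triangles (z00, z10, z11) and (z00, z01, z11) share the NW-SE diagonal;
  # for axis-aligned right triangles the cross product reduces to:
  area_tri <- function(dza, dzb) 0.5 * sqrt((s * dza)^2 + (s * dzb)^2 + s^4)
  a1 <- area_tri(z10 - z00, z11 - z10)
  a2 <- area_tri(z01 - z00, z11 - z01)
  sum(a1 + a2) / ((nr - 1) * (nc - 1) * s^2)
}

#' Flag height artifacts on a metric grid
#'
#' Cells with a 95th percentile height above 64 m or a mean height above
#' 40 m are physically implausible for subalpine forest and almost always
#' arise from horizontal misregistration near cliffs; they are masked and
#' excluded from selection, fitting, prediction and areal totals.
#'
#' @param grid metric grid data frame with `mean_height_m` and `p95`.
#' @return the grid with a logical `mask_flag` column set.
#' @export
mask_height_artifacts <- function(grid) {
  stopifnot(all(c("mean_height_m", "p95") %in% names(grid)))
  p95 <- grid$p95; mh <- grid$mean_height_m
  grid$mask_flag <- (!is.na(p95) & p95 > 64) | (!is.na(mh) & mh > 40)
  grid
}

#' Compute the 17-metric grid from a normalized point cloud
#'
#' Bins points into square cells, computes the height metrics per cell, adds
#' rumple from a per-cell 1 m CHM, and applies the artifact mask.
#'
#' @param points data frame with `x`, `y` (m) and normalized heights `z` (m).
#' @param cell_size_m grid cell size (m), default 30.
#' @param origin grid origin `c(x, y)` in meters.
#' @param chm_res_m CHM resolution for rumple (m).
#' @return data frame: cell indices and centers (m), the 17 metrics,
#'   `n_points`, `mask_flag`.
#' @export
compute_metric_grid <- function(points, cell_size_m = 30, origin = c(0, 0),
                                chm_res_m = 1) {
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  ix <- floor((points$x - origin[1]) / cell_size_m)
  iy <- floor((points$y - origin[2]) / cell_size_m)
  key <- paste(ix, iy)
  cells <- unique(data.frame(ix = ix, iy = iy, key = key))
  cells <- cells[order(cells$ix, cells$iy), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- key == cells$key[i]
    m <- compute_cell_metrics(points$z[sel])
    m$rumple <- cell_rumple(points[sel, ], cells$ix[i], cells$iy[i],
                            cell_size_m, origin, chm_res_m)
    m
  })
  grid <- do.call(rbind, rows)
  grid <- cbind(data.frame(ix = cells$ix, iy = cells$iy,
                           x_m = origin[1] + (cells$ix + 0.5) * cell_size_m,
                           y_m = origin[2] + (cells$iy + 0.5) * cell_size_m),
                grid)
  rownames(grid) <- NULL
  mask_height_artifacts(grid)
}

# CHM for one cell: highest return per fine cell, empty fine cells = ground.
cell_rumple <- function(pts, ix, iy, cell_size_m, origin, chm_res_m) {
  nf <- max(2L, ceiling(cell_size_m / chm_res_m))
  x0 <- origin[1] + ix * cell_size_m
  y0 <- origin[2] + iy * cell_size_m
  fx <- pmin(nf - 1L, pmax(0L, floor((pts$x - x0) / chm_res_m)))
  fy <- pmin(nf - 1L, pmax(0L, floor((pts$y - y0) / chm_res_m)))
  chm <- matrix(0, nf, nf)
  idx <- fy + nf * fx + 1L
  agg <- tapply(pts$z, idx, max)
  chm[as.integer(names(agg))] <- pmax(0, agg)
  compute_rumple(chm, chm_res_m)
}

#' Extract plot-level metric vectors from grid and points
#'
#' Zonal mode takes the area-weighted mean of the unmasked cells a circular
#' plot intersects (weights from a deterministic 1 m subsample of the
#' disc). Point-clip mode recomputes the metrics from the points inside the
#' plot boundary - except rumple, which is always zonal because of its
#' strong edge effects.
#'
#' @param center_m plot center `c(x, y)` in meters.
#' @param radius_m plot radius in meters.
#' @param grid metric grid from [compute_metric_grid()].
#' @param points point data frame (required for `mode = "point_clip"`).
#' @param mode `"zonal"` or `"point_clip"`.
#' @param cell_size_m grid cell size (m).
#' @param origin grid origin (m).
#' @return named numeric vector of the 17 metrics.
#' @export
extract_plot_metrics <- function(center_m, radius_m, grid, points = NULL,
                                 mode = c("zonal", "point_clip"),
                                 cell_size_m = 30, origin = c(0, 0)) {
  mode <- match.arg(mode)
  metric_cols <- c("canopy_cover_pct", "mean_height_m", "sd_height_m",
                   PCTL_NAMES, "rumple")
  # deterministic 1 m subsample of the disc -> per-cell overlap weights
  g <- seq(-radius_m + 0.5, radius_m - 0.5, by = 1)
  sub <- expand.grid(dx = g, dy = g, KEEP.OUT.ATTRS = FALSE)
  sub <- sub[sub$dx^2 + sub$dy^2 <= radius_m^2, ]
  if (nrow(sub) == 0L) sub <- data.frame(dx = 0, dy = 0)
  cx <- floor((center_m[1] + sub$dx - origin[1]) / cell_size_m)
  cy <- floor((center_m[2] + sub$dy - origin[2]) / cell_size_m)
  wt <- table(paste(cx, cy))
  gkey <- paste(grid$ix, grid$iy)
  hit <- match(names(wt), gkey)
  ok <- !is.na(hit) & !grid$mask_flag[hit]
  if (!any(ok)) stop("plot overlaps no unmasked grid cell", call. = FALSE)
  w <- as.numeric(wt[ok]) / sum(wt[ok])
  cells <- grid[hit[ok], , drop = FALSE]
  zonal <- vapply(metric_cols, function(cl) {
    v <- cells[[cl]]
    sum(w * v)  # NA heights propagate: undefined cells make the mean undefined
  }, numeric(1))
  if (mode == "zonal") return(zonal)

  if (is.null(points)) stop("point_clip mode needs the point cloud", call. = FALSE)
  inside <- (points$x - center_m[1])^2 + (points$y - center_m[2])^2 <= radius_m^2
  m <- compute_cell_metrics(points$z[inside])
  out <- unlist(m[c("canopy_cover_pct", "mean_height_m", "sd_height_m", PCTL_NAMES)])
  c(out, rumple = unname(zonal["rumple"]))
}
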