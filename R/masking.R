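#' Horn eight-neighbour gradient of a grid
#'
#' Computes x/y gradients with Horn's third-order finite-difference weights
#' (the GIS-standard slope operator); border pixels use replicated-edge
#' neighbours.
#' @keywords internal
horn_gradient <- function(z, cell_size) {
  nr <- nrow(z); nc <- ncol(z)
  # replicate-pad by one pixel
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sh <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  # neighbours named by compass position relative to each cell
  nw <- sh(0, 0); n_ <- sh(0, 1); ne <- sh(0, 2)
  w_ <- sh(1, 0);                 e_ <- sh(1, 2)
  sw <- sh(2, 0); s_ <- sh(2, 1); se <- sh(2, 2)
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cell_size)
  gy <- ((sw + 2 * s_ + se) - (nw + 2 * n_ + ne)) / (8 * cell_size)
  list(gx = gx, gy = gy)
}

#' Compute slope in degrees from a DEM
#'
#' Slope is `atan(sqrt(gx^2 + gy^2))` with Horn's eight-neighbour gradient.
#'
#' @param dem A `dem_raster` (elevation in metres, positive `cell_size`).
#' @return A `slope_raster` with per-pixel slope in degrees, in `[0, 90)`.
#' @export
compute_slope <- function(dem) {
  z <- dem$elevation
  if (nrow(z) < 3 || ncol(z) < 3)
    stopf("compute_slope: DEM must be at least 3x3 pixels")
  if (is.null(dem$cell_size) || dem$cell_size <= 0)
    stopf("compute_slope: DEM cell_size must be positive")
  if (any(!is.finite(z)))
    stopf("compute_slope: DEM contains non-finite elevations")
  g <- horn_gradient(z, dem$cell_size)
  structure(list(slope = atan(sqrt(g$gx^2 + g$gy^2)) * 180 / pi,
                 cell_size = dem$cell_size),
            class = "slope_raster")
}

#' Terrain plausibility mask for paddy rice
#'
#' Pixels with slope strictly greater than the threshold are masked out
#' (rice is not grown on such terrain); a pixel at exactly the threshold is
#' retained.
#'
#' @param slope A `slope_raster`.
#' @param threshold_deg Maximum retained slope in degrees (default 8).
#' @return Logical matrix, `TRUE` = pixel retained.
#' @export
slope_mask <- function(slope, threshold_deg = 8) {
  if (threshold_deg < 0)
    stopf("slope_mask: threshold must be nonnegative")
  slope$slope <= threshold_deg
}

#' Invalidate cloud-contaminated index observations
#'
#' Marks every index value at a QA-flagged (pixel, date) cell invalid. The
#' operation is idempotent and touches exactly `8 x #flagged pixel-dates`
#' cells on a previously all-valid stack.
#'
#' @param indices An `index_stack`.
#' @param qa Logical array `date x row x col`, `TRUE` = valid observation.
#' @return The `index_stack` with invalidated cells set `NA`/`valid = FALSE`.
#' @export
apply_cloud_mask <- function(indices, qa) {
  d <- dim(indices$values)
  if (!identical(dim(qa), c(d[1], d[3], d[4])))
    stopf("apply_cloud_mask: QA dims (%s) do not match index grid (%s)",
          paste(dim(qa), collapse = "x"),
          paste(d[c(1, 3, 4)], collapse = "x"))
  flagged <- !qa
  for (i in seq_len(d[2])) {
    v <- indices$values[, i, , ]
    v[flagged] <- NA_real_
    indices$values[, i, , ] <- v
    ok <- indices$valid[, i, , ]
    ok[flagged] <- FALSE
    indices$valid[, i, , ] <- ok
  }
  indices
}
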