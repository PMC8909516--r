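#' @keywords internal
scene_bands <- c("B1", "B3", "B4", "B5", "B6", "B7", "B8")

# Fixed vigor-to-reflectance mixing: each band is an affine blend between a
# soil endmember (vigor 0) and a full-canopy endmember (vigor 1). Chosen so
# NIR (B7, B8) increases with vigor, red (B4) decreases, red-edge (B5, B6)
# responds intermediately, and every Table-1-style denominator (B6 - B5,
# B5 - B1, B5, B4) stays bounded away from zero in the noise-free limit.
SOIL_REFL <- c(B1 = 0.06, B3 = 0.10, B4 = 0.15, B5 = 0.18,
               B6 = 0.22, B7 = 0.24, B8 = 0.25)
VEG_REFL  <- c(B1 = 0.03, B3 = 0.08, B4 = 0.04, B5 = 0.12,
               B6 = 0.30, B7 = 0.42, B8 = 0.48)
CLOUD_REFL <- 0.95       # bright flat spectrum written into contaminated cells
LABEL_LEVELS <- c(nonrice = 0L, rice_unstressed = 1L, rice_stressed = 2L)

# Double-logistic canopy vigor: green-up around DOY 140, senescence around
# DOY 268 (transplanting to harvest for a single-season paddy calendar).
vigor_curve <- function(doy, green_up = 140, green_rate = 0.10,
                        senesce = 268, senesce_rate = 0.09) {
  sigmoid(green_rate * (doy - green_up)) * sigmoid(senesce_rate * (senesce - doy))
}

# Stressed vigor: persistent multiplicative depression plus a Gaussian
# mid-season trough.
stressed_vigor <- function(v, doy, depression, center, width, depth) {
  depression * v * (1 - depth * exp(-(doy - center)^2 / (2 * width^2)))
}

#' Simulate a labelled multispectral scene time stack
#'
#' Generates a reflectance time stack over bands B1, B3, B4, B5, B6, B7, B8
#' together with per-date QA validity flags, a three-class label raster and a
#' smooth synthetic DEM. Rice pixels follow a shared double-logistic vigor
#' curve; stressed rice follows the same curve scaled down by
#' `stress_depression` and dented by a Gaussian June--August trough, so its
#' red-edge indices sit below the unstressed curve at every date with the
#' widest gap in mid season. Non-rice pixels keep a constant soil spectrum.
#' Cloud-contaminated (pixel, date) cells receive a bright flat spectrum and
#' `qa = FALSE`.
#'
#' @param config A [scene_config()].
#' @return A list with elements `stack` (class `reflectance_stack`: `values`
#'   array `date x band x row x col`, logical `qa` array `date x row x col`
#'   with `TRUE` = valid, `dates`, `bands`, `geotransform`, `cell_size`),
#'   `labels` (class `label_raster`) and `dem` (class `dem_raster`).
#' @export
simulate_scene <- function(config) {
  validate_scene_config(config)
  nr <- config$n_rows; nc <- config$n_cols
  doy <- config$dates
  nt <- length(doy); nb <- length(scene_bands)
  npix <- nr * nc

  local_seed(config$seed, {
    lab <- matrix(sample(LABEL_LEVELS, npix, replace = TRUE,
                         prob = config$class_fractions), nr, nc)

    v_un <- vigor_curve(doy)
    v_st <- stressed_vigor(v_un, doy, config$stress_depression,
                           config$trough_center_doy,
                           config$trough_width_days,
                           config$trough_depth)
    # per-class vigor trajectories, rows = date, cols = class 0/1/2
    v_class <- cbind(nonrice = rep(0, nt), unstressed = v_un, stressed = v_st)

    values <- array(NA_real_, dim = c(nt, nb, nr, nc),
                    dimnames = list(NULL, scene_bands, NULL, NULL))
    lab_idx <- as.vector(lab) + 1L
    for (t in seq_len(nt)) {
      v_pix <- v_class[t, lab_idx]            # length npix
      for (b in seq_len(nb)) {
        refl <- SOIL_REFL[b] + (VEG_REFL[b] - SOIL_REFL[b]) * v_pix
        values[t, b, , ] <- refl
      }
    }

    if (config$noise_sd > 0)
      values <- values + rnorm(length(values), sd = config$noise_sd)

    qa <- array(TRUE, dim = c(nt, nr, nc))
    if (config$cloud_prob > 0) {
      cloudy <- array(runif(nt * npix) < config$cloud_prob, dim = c(nt, nr, nc))
      qa[cloudy] <- FALSE
      for (b in seq_len(nb)) values[, b, , ][cloudy] <- CLOUD_REFL
    }
    values[values < 0] <- 0
    values[values > 1.2] <- 1.2

    dem <- simulate_dem(nr, nc, config$cell_size)

    stack <- structure(list(
      values = values, qa = qa, dates = doy, bands = scene_bands,
      geotransform = c(0, config$cell_size, 0, 0, 0, -config$cell_size),
      cell_size = config$cell_size
    ), class = "reflectance_stack")
    labels <- structure(list(labels = lab, levels = LABEL_LEVELS),
                        class = "label_raster")
    list(stack = stack, labels = labels, dem = dem)
  })
}

# Smooth random field from low-frequency cosines, rescaled so that about 10%
# of pixels exceed an 8-degree slope; guarantees the slope-mask path always
# has work to do. Draws from the active RNG stream.
simulate_dem <- function(n_rows, n_cols, cell_size, n_waves = 6L,
                         target_slope_deg = 8, exceed_fraction = 0.10) {
  r <- matrix(seq_len(n_rows), n_rows, n_cols)
  c_ <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  span <- max(n_rows, n_cols)
  z <- matrix(0, n_rows, n_cols)
  for (k in seq_len(n_waves)) {
    freq <- runif(2, 0.5, 2.5) / span
    phase <- runif(1, 0, 2 * pi)
    amp <- 1 / k
    z <- z + amp * cos(2 * pi * (freq[1] * r + freq[2] * c_) + phase)
  }
  if (n_rows >= 3 && n_cols >= 3) {
    g <- horn_gradient(z, cell_size)
    q <- stats::quantile(sqrt(g$gx^2 + g$gy^2), 1 - exceed_fraction)
    if (q > 0) z <- z * tan(target_slope_deg * pi / 180) / q
  }
  structure(list(elevation = z + 100, cell_size = cell_size),
            class = "dem_raster")
}

#' @export
print.reflectance_stack <- function(x, ...) {
  d <- dim(x$values)
  cat("<reflectance_stack> ", d[1], " dates x ", d[2], " bands x ",
      d[3], "x", d[4], " pixels\n", sep = "")
  cat("  bands: ", paste(x$bands, collapse = ", "), "\n", sep = "")
  cat("  DOY ", min(x$dates), "-", max(x$dates),
      "; QA-invalid fraction ", signif(mean(!x$qa), 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.label_raster <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$levels, labels = names(x$levels)))
  cat("<label_raster> ", nrow(x$labels), "x", ncol(x$labels), " pixels: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.dem_raster <- function(x, ...) {
  cat("<dem_raster> ", nrow(x$elevation), "x", ncol(x$elevation),
      " pixels, cell ", x$cell_size, " m, elevation ",
      signif(min(x$elevation), 4), "-", signif(max(x$elevation), 4), " m\n",
      sep = "")
  invisible(x)
}
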