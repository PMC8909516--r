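#' Configuration for the synthetic scene generator
#'
#' Defines the study conditions a generated scene emulates: an April--October
#' acquisition calendar, three pixel classes (non-rice, unstressed rice,
#' stressed rice), a persistent multiplicative vigor depression plus a
#' mid-season Gaussian trough for stressed pixels, additive reflectance noise,
#' and independent per-(pixel, date) cloud contamination.
#'
#' Default class fractions follow the labelled pixel counts of the study
#' scene (153,300 stressed and 79,918 unstressed rice pixels in a
#' 1000 x 1000 grid, remainder non-rice). The default calendar is 33 dates
#' evenly spread over day-of-year 95--288 (early April to mid October).
#'
#' @param n_rows,n_cols Grid size in pixels.
#' @param dates Strictly increasing day-of-year acquisition dates.
#' @param class_fractions Length-3 proportions (non-rice, unstressed rice,
#'   stressed rice); must sum to 1.
#' @param stress_depression Multiplicative vigor reduction applied to stressed
#'   pixels over the whole season, in (0, 1]; 1 disables the persistent
#'   depression.
#' @param trough_center_doy,trough_width_days,trough_depth Centre (day of
#'   year), Gaussian width (days) and relative depth (0--1) of the extra
#'   mid-season vigor dip of stressed pixels.
#' @param noise_sd Standard deviation of additive Gaussian reflectance noise.
#' @param cloud_prob Per-(pixel, date) probability of cloud contamination,
#'   in [0, 1).
#' @param cell_size Ground cell size in metres (also used for the DEM).
#' @param seed Integer seed; scenes are bit-identical given the same seed.
#'
#' @return A validated object of class `scene_config`.
#' @export
scene_config <- function(n_rows = 64L,
                         n_cols = 64L,
                         dates = round(seq(95, 288, length.out = 33)),
                         class_fractions = c(nonrice = 0.767,
                                             rice_unstressed = 0.080,
                                             rice_stressed = 0.153),
                         stress_depression = 0.85,
                         trough_center_doy = 200,
                         trough_width_days = 25,
                         trough_depth = 0.30,
                         noise_sd = 0.01,
                         cloud_prob = 0.05,
                         cell_size = 10,
                         seed = 1L) {
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    dates = as.numeric(dates),
    class_fractions = as.numeric(class_fractions),
    stress_depression = stress_depression,
    trough_center_doy = trough_center_doy,
    trough_width_days = trough_width_days,
    trough_depth = trough_depth,
    noise_sd = noise_sd,
    cloud_prob = cloud_prob,
    cell_size = cell_size,
    seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  if (cfg$n_rows < 1L || cfg$n_cols < 1L)
    stop("scene_config: grid must have at least one pixel", call. = FALSE)
  if (length(cfg$dates) < 2L || any(diff(cfg$dates) <= 0))
    stop("scene_config: dates must be strictly increasing", call. = FALSE)
  if (length(cfg$class_fractions) != 3L ||
      abs(sum(cfg$class_fractions) - 1) > 1e-8 ||
      any(cfg$class_fractions < 0))
    stop("scene_config: class_fractions must be 3 nonnegative values summing to 1",
         call. = FALSE)
  if (cfg$stress_depression <= 0 || cfg$stress_depression > 1)
    stop("scene_config: stress_depression must lie in (0, 1]", call. = FALSE)
  if (cfg$trough_depth < 0 || cfg$trough_depth >= 1)
    stop("scene_config: trough_depth must lie in [0, 1)", call. = FALSE)
  if (cfg$trough_width_days <= 0)
    stop("scene_config: trough_width_days must be positive", call. = FALSE)
  if (cfg$cloud_prob < 0 || cfg$cloud_prob >= 1)
    stop("scene_config: cloud_prob must lie in [0, 1)", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("scene_config: noise_sd must be nonnegative", call. = FALSE)
  if (cfg$cell_size <= 0)
    stop("scene_config: cell_size must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config> ", x$n_rows, "x", x$n_cols, " pixels, ",
      length(x$dates), " dates (DOY ", min(x$dates), "-", max(x$dates), ")\n",
      sep = "")
  cat("  class fractions: nonrice ", x$class_fractions[1],
      ", unstressed ", x$class_fractions[2],
      ", stressed ", x$class_fractions[3], "\n", sep = "")
  cat("  stress: depression ", x$stress_depression,
      ", trough depth ", x$trough_depth,
      " @ DOY ", x$trough_center_doy,
      " (width ", x$trough_width_days, " d)\n", sep = "")
  cat("  noise_sd ", x$noise_sd, ", cloud_prob ", x$cloud_prob,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
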