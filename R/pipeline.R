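#' End-to-end pipeline configuration
#'
#' @param scene A [scene_config()] used when no `scene_dir` is given.
#' @param scene_dir Optional directory holding a scene written by
#'   [write_scene()]; when given, it is read instead of simulating.
#' @param gru A [gru_config()].
#' @param train_fraction,split_seed Train/test split settings (default 80/20,
#'   stratified).
#' @param max_slope_deg Slope threshold in degrees; steeper pixels are removed
#'   (default 8).
#' @param rice_only If `TRUE`, train and classify only rice pixels
#'   (2-class stressed vs unstressed); otherwise all three classes enter the
#'   model.
#' @param out_dir Artifact directory.
#' @param save_scene If `TRUE`, the simulated scene is also written under
#'   `out_dir/scene`.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(), scene_dir = NULL,
                            gru = gru_config(), train_fraction = 0.8,
                            split_seed = 1L, max_slope_deg = 8,
                            rice_only = FALSE, out_dir = tempfile("ricegru_"),
                            save_scene = FALSE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("pipeline_config: train_fraction must lie strictly between 0 and 1")
  if (!is.null(scene)) validate_scene_config(scene)
  structure(list(scene = scene, scene_dir = scene_dir, gru = gru,
                 train_fraction = train_fraction,
                 split_seed = as.integer(split_seed),
                 max_slope_deg = max_slope_deg, rice_only = rice_only,
                 out_dir = out_dir, save_scene = save_scene),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full stress-detection pipeline
#'
#' Simulates (or reads) a scene, computes the eight indices, applies cloud and
#' slope masks, builds standardized per-pixel sequences with an 80/20
#' stratified split, trains the GRU, classifies the scene, and evaluates the
#' test-set predictions with a confusion matrix, per-class metrics and Kappa.
#' All artifacts (metric report, confusion counts, training history,
#' classified map, provenance record, run log) are written under
#' `config$out_dir`; re-running with the same configuration reproduces every
#' numeric output exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `model`, `report` (test-set
#'   `metric_report`), `map`, `series` sizes and the artifact directory.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  scene <- run_stage("scene", {
    if (!is.null(config$scene_dir)) {
      say("reading scene from ", config$scene_dir)
      read_scene(config$scene_dir)
    } else {
      say("simulating scene (seed ", config$scene$seed, ")")
      simulate_scene(config$scene)
    }
  })
  if (config$save_scene)
    run_stage("write_scene", write_scene(scene$stack, scene$labels, scene$dem,
                                         file.path(out, "scene")))

  indices <- run_stage("indices", compute_indices(scene$stack))
  indices <- run_stage("cloud_mask", apply_cloud_mask(indices, scene$stack$qa))
  say("indices computed; invalid cell fraction ",
      signif(mean(!indices$valid), 4))

  slope <- run_stage("slope", compute_slope(scene$dem))
  mask <- run_stage("slope_mask", slope_mask(slope, config$max_slope_deg))
  say("slope mask removed ", sum(!mask), " of ", length(mask), " pixels (> ",
      config$max_slope_deg, " deg)")
  if (config$rice_only) mask <- mask & scene$labels$labels > 0L

  series <- run_stage("build_series",
                      build_series(indices, scene$labels, mask))
  say("built ", dim(series$x)[1], " sequences (", series$n_dropped,
      " pixels dropped for lack of valid observations)")
  split <- run_stage("split", split_dataset(series, config$train_fraction,
                                            stratified = TRUE,
                                            seed = config$split_seed))
  std <- run_stage("standardize", standardize_series(split$train, split$test))

  model <- run_stage("train", train_gru(std$train, std$test, config$gru))
  say("trained ", nrow(model$history), " epochs; best epoch ",
      model$best_epoch)

  y_pred <- run_stage("predict", predict_series(model, std$test))
  k <- length(model$classes)
  code_of <- function(v) match(v, model$classes) - 1L
  cm <- run_stage("evaluate",
                  confusion(code_of(std$test$label), code_of(y_pred), k,
                            class_names = names(LABEL_LEVELS)[
                              match(model$classes, LABEL_LEVELS)]))
  report <- metric_report(cm)
  say("test overall accuracy ", sprintf("%.2f%%", 100 * report$overall_accuracy),
      ", Kappa ", sprintf("%.2f%%", 100 * report$kappa))

  map <- run_stage("predict_map", predict_map(model, series))

  # artifacts
  write_metric_report(report, file.path(out, "metrics_test.csv"))
  utils::write.csv(as.data.frame(unclass(cm)),
                   file.path(out, "confusion_test.csv"))
  hist_out <- model$history
  hist_out$seconds <- NULL                       # wall time is not a result
  utils::write.csv(hist_out, file.path(out, "history.csv"), row.names = FALSE)
  tiff::writeTIFF(map / 255, file.path(out, "classified_map.tif"),
                  bits.per.sample = 32L)
  prov <- list(package = "ricegru",
               version = as.character(utils::packageVersion("ricegru")),
               scene_seed = if (is.null(config$scene_dir)) config$scene$seed
                            else NULL,
               scene_dir = config$scene_dir,
               split_seed = config$split_seed,
               train_fraction = config$train_fraction,
               max_slope_deg = config$max_slope_deg,
               rice_only = config$rice_only,
               gru = unclass(config$gru),
               scene = if (is.null(config$scene_dir)) unclass(config$scene)
                       else NULL)
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(list(model = model, report = report, map = map,
                 n_train = dim(std$train$x)[1], n_test = dim(std$test$x)[1],
                 out_dir = out))
}

#' Plot training loss and accuracy curves
#'
#' Two-panel base-graphics plot of per-epoch train/test loss and train/test
#' overall accuracy.
#'
#' @param model A `gru_model`.
#' @export
plot_history <- function(model) {
  h <- model$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$test_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "cross-entropy loss", main = "Loss")
  graphics::legend("topright", c("train", "test"), col = c("black", "red"),
                   lty = 1, bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_accuracy, h$test_accuracy),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "overall accuracy",
                    main = "Accuracy", ylim = c(0, 1))
  graphics::legend("bottomright", c("train", "test"), col = c("black", "red"),
                   lty = 1, bty = "n")
  invisible(model)
}
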