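#' Build fixed-length per-pixel index sequences
#'
#' Extracts, for every retained pixel, the `n_dates x 8` matrix of index
#' values and fills cloud- or formula-invalidated cells by per-index linear
#' interpolation over the shared date grid, with nearest-valid extrapolation
#' at the sequence ends. Originally valid cells are never altered. Pixels for
#' which any index channel has zero valid observations cannot be filled and
#' are dropped; the count is reported so the cost of cloud removal stays
#' visible.
#'
#' @param indices An `index_stack`.
#' @param labels A `label_raster` on the same grid.
#' @param pixel_mask Logical matrix (`TRUE` = keep); default keeps all pixels.
#' @return An object of class `index_series_set`: `x` array
#'   `(sample, date, index)`, integer `label`, pixel `row`/`col`, per-sample
#'   `gap_fraction` (share of interpolated cells), `dates`, `indices`, and
#'   `n_dropped`.
#' @export
build_series <- function(indices, labels, pixel_mask = NULL) {
  d <- dim(indices$values)
  nt <- d[1]; ni <- d[2]; nr <- d[3]; nc <- d[4]
  if (!identical(dim(labels$labels), c(nr, nc)))
    stopf("build_series: label grid (%s) does not match index grid (%s)",
          paste(dim(labels$labels), collapse = "x"),
          paste(c(nr, nc), collapse = "x"))
  if (is.null(pixel_mask)) pixel_mask <- matrix(TRUE, nr, nc)
  if (!identical(dim(pixel_mask), c(nr, nc)))
    stopf("build_series: pixel_mask grid does not match index grid")

  keep <- which(pixel_mask, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    stopf("build_series: pixel mask retains no pixels")

  dates <- indices$dates
  x <- array(NA_real_, dim = c(nrow(keep), nt, ni))
  gap_fraction <- numeric(nrow(keep))
  ok_sample <- logical(nrow(keep))

  for (s in seq_len(nrow(keep))) {
    r <- keep[s, 1]; c_ <- keep[s, 2]
    vals <- matrix(indices$values[, , r, c_], nt, ni)
    good <- matrix(indices$valid[, , r, c_], nt, ni)
    if (any(colSums(good) == 0L)) next           # unfillable channel -> drop
    for (i in seq_len(ni)) {
      gi <- good[, i]
      if (all(gi)) {
        x[s, , i] <- vals[, i]
      } else if (sum(gi) == 1L) {
        x[s, , i] <- vals[which(gi), i]          # single observation: constant fill
      } else {
        x[s, , i] <- stats::approx(dates[gi], vals[gi, i], xout = dates,
                                   method = "linear", rule = 2, ties = "ordered")$y
        x[s, gi, i] <- vals[gi, i]               # valid cells pass through untouched
      }
    }
    gap_fraction[s] <- mean(!good)
    ok_sample[s] <- TRUE
  }

  if (!any(ok_sample))
    stopf("build_series: every pixel was dropped (no valid observations)")

  structure(list(
    x = x[ok_sample, , , drop = FALSE],
    label = unname(labels$labels[keep[ok_sample, , drop = FALSE]]),
    row = unname(keep[ok_sample, 1]), col = unname(keep[ok_sample, 2]),
    gap_fraction = gap_fraction[ok_sample],
    dates = dates, indices = indices$indices,
    n_dropped = sum(!ok_sample),
    grid_dim = c(nr, nc)
  ), class = "index_series_set")
}

series_subset <- function(series, idx) {
  out <- series
  out$x <- series$x[idx, , , drop = FALSE]
  out$label <- series$label[idx]
  out$row <- series$row[idx]
  out$col <- series$col[idx]
  out$gap_fraction <- series$gap_fraction[idx]
  out
}

#' @export
print.index_series_set <- function(x, ...) {
  cat("<index_series_set> ", dim(x$x)[1], " samples x ", dim(x$x)[2],
      " dates x ", dim(x$x)[3], " indices (", x$n_dropped, " pixels dropped)\n",
      sep = "")
  print(table(x$label))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits samples into disjoint, exhaustive train and test sets, stratified by
#' label (default) and deterministic given the seed. Per class, the train
#' count is `floor(n_class * train_fraction)` (capped at `n_class - 1` so the
#' test set is never empty).
#'
#' @param series An `index_series_set`.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.8).
#' @param stratified Stratify by label (default `TRUE`).
#' @param seed Integer RNG seed.
#' @return List with `train` and `test` (`index_series_set`s).
#' @export
split_dataset <- function(series, train_fraction = 0.8, stratified = TRUE,
                          seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("split_dataset: train_fraction must lie strictly between 0 and 1")
  n <- length(series$label)
  local_seed(seed, {
    if (stratified) {
      counts <- table(series$label)
      if (any(counts < 2L))
        stopf("split_dataset: class %s has fewer than 2 samples; cannot stratify",
              names(counts)[which(counts < 2L)[1]])
      train_idx <- integer(0)
      for (cl in as.integer(names(counts))) {
        idx <- which(series$label == cl)
        n_tr <- min(floor(length(idx) * train_fraction), length(idx) - 1L)
        n_tr <- max(n_tr, 1L)
        train_idx <- c(train_idx, sample(idx, n_tr))
      }
    } else {
      n_tr <- min(max(floor(n * train_fraction), 1L), n - 1L)
      train_idx <- sample.int(n, n_tr)
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_len(n), train_idx)
    list(train = series_subset(series, train_idx),
         test = series_subset(series, test_idx))
  })
}

#' Standardize index channels using training statistics
#'
#' Centres and scales each of the 8 index channels to mean 0 / sd 1, with
#' moments estimated on the training samples only (pooled over samples and
#' dates) and applied unchanged to the test set. Channels with zero training
#' variance fall back to scale 1.
#'
#' @param train,test `index_series_set`s from [split_dataset()].
#' @return List with scaled `train` and `test` plus the per-index `center`
#'   and `scale` used.
#' @export
standardize_series <- function(train, test) {
  if (dim(train$x)[1] == 0L)
    stopf("standardize_series: training set is empty")
  ni <- dim(train$x)[3]
  center <- numeric(ni); scale <- numeric(ni)
  for (i in seq_len(ni)) {
    v <- train$x[, , i]
    center[i] <- mean(v)
    s <- stats::sd(as.vector(v))
    scale[i] <- if (!is.finite(s) || s == 0) 1 else s
    train$x[, , i] <- (train$x[, , i] - center[i]) / scale[i]
    test$x[, , i] <- (test$x[, , i] - center[i]) / scale[i]
  }
  names(center) <- names(scale) <- train$indices
  list(train = train, test = test, center = center, scale = scale)
}
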