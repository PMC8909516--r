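adam_init <- function(w) {
  zero <- lapply(w, function(m) if (is.matrix(m)) matrix(0, nrow(m), ncol(m))
                 else numeric(length(m)))
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(w)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    w[[nm]] <- w[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(w = w, state = state)
}

# Forward a whole dataset in chunks; returns loss, predictions (1..k) and probs.
evaluate_set <- function(w, x, y, chunk = 1024L) {
  n <- dim(x)[1]
  pred <- integer(n)
  loss_sum <- 0
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    idx <- s:e
    xb <- x[idx, , , drop = FALSE]
    probs <- gru_forward_batch(w, xb)$probs
    pick <- cbind(seq_along(idx), y[idx])
    loss_sum <- loss_sum - sum(log(pmax(probs[pick], .Machine$double.xmin)))
    pred[idx] <- apply(probs, 1, which.max)
  }
  list(loss = loss_sum / n, pred = pred, accuracy = mean(pred == y))
}

#' Train the GRU stress classifier
#'
#' Minimizes multiclass cross-entropy by mini-batch Adam over the training
#' sequences, recording train/test loss, overall accuracy and per-class
#' accuracy after every epoch. Training stops at `max_epochs` or after
#' `patience` epochs without test-loss improvement; the returned model carries
#' the epoch-best weights by test loss. Fully deterministic given
#' `config$seed`.
#'
#' @param train,test Standardized `index_series_set`s (see
#'   [standardize_series()]).
#' @param config A [gru_config()]; `input_size` must match the number of index
#'   channels and `n_classes` the number of distinct training labels.
#' @return An object of class `gru_model`: `weights`, `config`, `classes`
#'   (original label codes in column order) and `history` (one row per epoch:
#'   losses, accuracies, per-class test accuracies, epoch time).
#' @export
train_gru <- function(train, test, config = gru_config()) {
  if (dim(train$x)[1] == 0L || dim(test$x)[1] == 0L)
    stopf("train_gru: train and test sets must be non-empty")
  if (dim(train$x)[3] != config$input_size)
    stopf("train_gru: %d feature channels but config$input_size = %d",
          dim(train$x)[3], config$input_size)
  classes <- sort(unique(train$label))
  if (length(classes) != config$n_classes)
    stopf("train_gru: %d classes in training labels but config$n_classes = %d",
          length(classes), config$n_classes)
  y_tr <- match(train$label, classes)
  y_te <- match(test$label, classes)
  if (anyNA(y_te))
    stopf("train_gru: test set contains labels absent from the training set")

  n_tr <- dim(train$x)[1]
  local_seed(config$seed, {
    w <- gru_init(config, seed = stats::runif(1, 1, 2^30))
    opt <- adam_init(w)
    history <- vector("list", config$max_epochs)
    best <- list(loss = Inf, w = w, epoch = 0L)
    stall <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      t0 <- proc.time()[["elapsed"]]
      order_ <- sample.int(n_tr)
      for (s in seq(1L, n_tr, by = config$batch_size)) {
        idx <- order_[s:min(s + config$batch_size - 1L, n_tr)]
        lg <- gru_loss_grad(w, train$x[idx, , , drop = FALSE], y_tr[idx])
        if (!is.finite(lg$loss))
          stopf("train_gru: non-finite loss at epoch %d; training diverged",
                epoch)
        upd <- adam_step(w, lg$grad, opt, config$learning_rate)
        w <- upd$w; opt <- upd$state
      }

      ev_tr <- evaluate_set(w, train$x, y_tr)
      ev_te <- evaluate_set(w, test$x, y_te)
      per_class <- vapply(seq_along(classes), function(k) {
        in_k <- y_te == k
        if (!any(in_k)) NA_real_ else mean(ev_te$pred[in_k] == k)
      }, numeric(1))
      names(per_class) <- paste0("test_acc_class_", classes)
      history[[epoch]] <- c(epoch = epoch,
                            train_loss = ev_tr$loss, test_loss = ev_te$loss,
                            train_accuracy = ev_tr$accuracy,
                            test_accuracy = ev_te$accuracy,
                            per_class,
                            seconds = proc.time()[["elapsed"]] - t0)

      if (ev_te$loss < best$loss - 1e-12) {
        best <- list(loss = ev_te$loss, w = w, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }

    history <- as.data.frame(do.call(rbind, history[!vapply(history, is.null,
                                                            logical(1))]))
    structure(list(weights = best$w, config = config, classes = classes,
                   best_epoch = best$epoch, history = history),
              class = "gru_model")
  })
}

#' @export
print.gru_model <- function(x, ...) {
  cfg <- x$config
  cat("<gru_model> d=", cfg$input_size, ", h=", cfg$hidden_size,
      ", head=", cfg$head_size, ", classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  cat("  ", gru_param_count(cfg$input_size, cfg$hidden_size, cfg$head_size,
                            cfg$n_classes),
      " parameters; ", nrow(x$history), " epochs trained (best epoch ",
      x$best_epoch, ")\n", sep = "")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat("  final test accuracy ", round(last$test_accuracy, 4),
        ", test loss ", signif(last$test_loss, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Predict class labels for an index series set
#'
#' @param model A `gru_model`.
#' @param series An `index_series_set` with the model's feature order.
#' @return Integer vector of predicted class codes (the original label codes).
#' @export
predict_series <- function(model, series) {
  if (dim(series$x)[3] != model$config$input_size)
    stopf("predict_series: %d feature channels but model expects %d",
          dim(series$x)[3], model$config$input_size)
  ev <- gru_forward_batch(model$weights, series$x)
  model$classes[apply(ev$probs, 1, which.max)]
}

#' Classify every retained pixel into a map
#'
#' Runs the model over all samples and writes the predicted class code into a
#' raster grid; pixels excluded by masking (absent from `series`) carry the
#' no-data code 255. Argmax ties break toward the lowest class index.
#'
#' @param model A `gru_model`.
#' @param series An `index_series_set` carrying pixel coordinates.
#' @param grid_dim `c(n_rows, n_cols)`; defaults to the grid recorded in
#'   `series`.
#' @return Integer matrix map with classes and 255 = no data.
#' @export
predict_map <- function(model, series, grid_dim = series$grid_dim) {
  if (is.null(grid_dim))
    stopf("predict_map: grid dimensions unknown; supply grid_dim")
  pred <- predict_series(model, series)
  map <- matrix(255L, grid_dim[1], grid_dim[2])
  map[cbind(series$row, series$col)] <- as.integer(pred)
  map
}
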