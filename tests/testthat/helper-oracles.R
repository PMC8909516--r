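# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: indices are computed scalar-by-scalar from the
# printed formulas, metrics by explicit counting loops, gradients by central
# finite differences.

# Scalar spectral-index oracle: one pixel, one date, named band values.
oracle_indices <- function(b) {
  c(REP = 700 + 40 * (((b[["B7"]] - b[["B4"]]) / 2 - b[["B5"]]) /
                        (b[["B6"]] - b[["B5"]])),
    CIred_edge = b[["B7"]] / b[["B5"]] - 1,
    MSR = (b[["B6"]] - b[["B1"]]) / (b[["B5"]] - b[["B1"]]),
    MCARI = ((b[["B5"]] - b[["B4"]]) - 0.2 * (b[["B5"]] - b[["B3"]])) *
      (b[["B5"]] / b[["B4"]]),
    NDVI = (b[["B8"]] - b[["B4"]]) / (b[["B8"]] + b[["B4"]]),
    RDVI = (b[["B7"]] - b[["B4"]]) / (b[["B7"]] + b[["B4"]]),
    NDRE1 = (b[["B6"]] - b[["B5"]]) / (b[["B6"]] + b[["B5"]]),
    NDRE2 = (b[["B7"]] - b[["B5"]]) / (b[["B7"]] + b[["B5"]]))
}

# Build a reflectance_stack directly from a values array (bypassing the
# simulator) for controlled-input tests.
make_stack <- function(values, qa = NULL, dates = NULL) {
  d <- dim(values)
  if (is.null(qa)) qa <- array(TRUE, dim = d[c(1, 3, 4)])
  if (is.null(dates)) dates <- seq(100, by = 6, length.out = d[1])
  structure(list(values = values, qa = qa, dates = dates,
                 bands = dimnames(values)[[2]],
                 geotransform = c(0, 10, 0, 0, 0, -10), cell_size = 10),
            class = "reflectance_stack")
}

random_stack <- function(nt = 3, nr = 8, nc = 8, seed = 1) {
  set.seed(seed)
  bands <- c("B1", "B3", "B4", "B5", "B6", "B7", "B8")
  values <- array(runif(nt * 7 * nr * nc, 0.01, 1.0),
                  dim = c(nt, 7, nr, nc),
                  dimnames = list(NULL, bands, NULL, NULL))
  make_stack(values)
}

# Pair-counting metric oracle: everything from explicit loops over samples.
oracle_metrics <- function(y_true, y_pred, k) {
  n <- length(y_true)
  cm <- matrix(0, k, k)
  for (i in seq_len(n)) cm[y_pred[i] + 1, y_true[i] + 1] <-
      cm[y_pred[i] + 1, y_true[i] + 1] + 1
  overall <- 0
  for (i in seq_len(n)) if (y_true[i] == y_pred[i]) overall <- overall + 1
  overall <- overall / n
  per_class <- lapply(seq_len(k) - 1, function(cl) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_len(n)) {
      if (y_pred[i] == cl && y_true[i] == cl) tp <- tp + 1
      else if (y_pred[i] == cl) fp <- fp + 1
      else if (y_true[i] == cl) fn <- fn + 1
      else tn <- tn + 1
    }
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
          else 2 * prec * rec / (prec + rec)
    c(accuracy = (tp + tn) / n, precision = prec, recall = rec, f1 = f1)
  })
  po <- overall
  pe <- 0
  for (cl in seq_len(k)) pe <- pe + sum(cm[cl, ]) * sum(cm[, cl]) / n^2
  kappa <- (po - pe) / (1 - pe)
  list(cm = cm, overall = overall, per_class = per_class, kappa = kappa)
}

# Central finite-difference gradient of the GRU loss over every parameter.
fd_gradient <- function(w, x, y, eps = 1e-4) {
  loss_fn <- ricegru:::gru_loss
  g <- lapply(w, function(m) { m[] <- 0; m })
  for (nm in names(w)) {
    for (j in seq_along(w[[nm]])) {
      wp <- w; wp[[nm]][j] <- wp[[nm]][j] + eps
      wm <- w; wm[[nm]][j] <- wm[[nm]][j] - eps
      g[[nm]][j] <- (loss_fn(wp, x, y) - loss_fn(wm, x, y)) / (2 * eps)
    }
  }
  g
}

max_rel_grad_err <- function(analytic, numeric_, floor = 1e-8) {
  max(vapply(names(analytic), function(nm) {
    max(abs(analytic[[nm]] - numeric_[[nm]]) /
          pmax(abs(analytic[[nm]]), abs(numeric_[[nm]]), floor))
  }, numeric(1)))
}

# Random small GRU instance for gradient checks.
random_gru_instance <- function(seed, d = 3, h = 4, nt = 5, n = 2, k = 3) {
  set.seed(seed)
  cfg <- gru_config(input_size = d, hidden_size = h, batch_size = n,
                    n_classes = k, head_size = max(h %/% 2, 2), seed = seed)
  w <- gru_init(cfg, seed = seed)
  w$br <- rnorm(h, sd = 0.3); w$bz <- rnorm(h, sd = 0.3)
  w$bh <- rnorm(h, sd = 0.3)
  w$b1 <- rnorm(cfg$head_size, sd = 0.3); w$b2 <- rnorm(k, sd = 0.3)
  list(w = w, x = array(rnorm(n * nt * d), dim = c(n, nt, d)),
       y = sample.int(k, n, replace = TRUE), cfg = cfg)
}

# Published validation count tables (rows = classified, cols = reference;
# class order: nonstressed rice, stressed rice).
validation_table_2020 <- function()
  as_confusion(matrix(c(291, 31, 44, 629), 2, 2, byrow = TRUE),
               c("nonstressed", "stressed"))
validation_table_2021 <- function()
  as_confusion(matrix(c(182, 43, 32, 597), 2, 2, byrow = TRUE),
               c("nonstressed", "stressed"))
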