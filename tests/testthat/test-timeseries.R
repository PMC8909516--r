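# A small index stack with controllable validity, one index channel at a
# time being easiest to reason about.
tiny_index_stack <- function(values, valid = NULL, dates = NULL) {
  # values: nt x ni x nr x nc
  if (is.null(valid)) valid <- array(TRUE, dim = dim(values))
  if (is.null(dates)) dates <- seq_len(dim(values)[1])
  structure(list(values = values, valid = valid, dates = dates,
                 indices = paste0("I", seq_len(dim(values)[2]))),
            class = "index_stack")
}

tiny_labels <- function(nr, nc, value = 1L)
  structure(list(labels = matrix(value, nr, nc),
                 levels = c(nonrice = 0L, rice_unstressed = 1L,
                            rice_stressed = 2L)),
            class = "label_raster")

test_that("gap-free input passes through build_series untouched", {
  set.seed(1)
  v <- array(rnorm(5 * 2 * 3 * 3), dim = c(5, 2, 3, 3))
  ser <- build_series(tiny_index_stack(v), tiny_labels(3, 3))
  expect_identical(dim(ser$x), c(9L, 5L, 2L))
  expect_equal(ser$x[1, , ], v[, , 1, 1])
  expect_equal(ser$x[5, , ], v[, , 2, 2])   # column-major pixel order
  expect_true(all(ser$gap_fraction == 0))
  expect_identical(ser$n_dropped, 0L)
})

test_that("interior gaps fill by linear interpolation, edge gaps by nearest valid", {
  v <- array(0, dim = c(4, 1, 1, 1))
  v[, 1, 1, 1] <- c(99, 0.2, NA, 0.4)      # leading invalid, one interior gap
  valid <- array(TRUE, dim = dim(v))
  valid[1, 1, 1, 1] <- FALSE
  valid[3, 1, 1, 1] <- FALSE
  ser <- build_series(tiny_index_stack(v, valid, dates = c(10, 20, 30, 40)),
                      tiny_labels(1, 1))
  expect_equal(as.vector(ser$x[1, , 1]), c(0.2, 0.2, 0.3, 0.4))
  expect_equal(ser$gap_fraction, 0.5)
})

test_that("gap filling never alters originally valid cells", {
  set.seed(3)
  sc <- simulate_scene(scene_config(n_rows = 8, n_cols = 8, cloud_prob = 0.2,
                                    seed = 3))
  ix <- apply_cloud_mask(compute_indices(sc$stack), sc$stack$qa)
  ser <- build_series(ix, sc$labels)
  for (s in seq_len(min(10, dim(ser$x)[1]))) {
    r <- ser$row[s]; c_ <- ser$col[s]
    good <- ix$valid[, , r, c_]
    vals <- ix$values[, , r, c_]
    expect_identical(ser$x[s, , ][good], vals[good])
  }
})

test_that("pixels with an unfillable channel are dropped and counted", {
  v <- array(1, dim = c(3, 2, 2, 1))
  valid <- array(TRUE, dim = dim(v))
  valid[, 2, 1, 1] <- FALSE                 # channel 2 of pixel (1,1): no data
  ser <- build_series(tiny_index_stack(v, valid), tiny_labels(2, 1))
  expect_identical(dim(ser$x)[1], 1L)
  expect_identical(ser$n_dropped, 1L)
  expect_identical(ser$row, 2L)

  valid[] <- FALSE
  expect_error(build_series(tiny_index_stack(v, valid), tiny_labels(2, 1)),
               "every pixel was dropped")
})

test_that("stratified split is a deterministic, exhaustive, disjoint 80/20 partition", {
  set.seed(5)
  n_per <- 100L
  v <- array(rnorm(4 * 1 * 300), dim = c(4, 1, 300, 1))
  labels <- structure(list(labels = matrix(rep(0:2, each = n_per), 300, 1),
                           levels = c(a = 0L, b = 1L, c = 2L)),
                      class = "label_raster")
  ser <- build_series(tiny_index_stack(v), labels)

  sp <- split_dataset(ser, 0.8, seed = 7)
  expect_identical(dim(sp$train$x)[1], 240L)
  expect_identical(dim(sp$test$x)[1], 60L)
  for (cl in 0:2) {
    expect_identical(sum(sp$train$label == cl), 80L)
    expect_identical(sum(sp$test$label == cl), 20L)
  }
  # partition: union = input, intersection empty (pixel coordinates are keys)
  key <- function(s) paste(s$row, s$col)
  expect_setequal(c(key(sp$train), key(sp$test)), key(ser))
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)

  sp2 <- split_dataset(ser, 0.8, seed = 7)
  expect_identical(sp$train$row, sp2$train$row)
  sp3 <- split_dataset(ser, 0.8, seed = 8)
  expect_false(identical(sp$train$row, sp3$train$row))
})

test_that("split proportions stay within one sample of floor(n * fraction) per class", {
  v <- array(rnorm(3 * 1 * 47), dim = c(3, 1, 47, 1))
  labels <- structure(list(labels = matrix(c(rep(0L, 13), rep(1L, 21),
                                             rep(2L, 13)), 47, 1),
                           levels = c(a = 0L, b = 1L, c = 2L)),
                      class = "label_raster")
  ser <- build_series(tiny_index_stack(v), labels)
  sp <- split_dataset(ser, 0.7, seed = 1)
  for (cl in 0:2) {
    n_cl <- sum(ser$label == cl)
    expect_lte(abs(sum(sp$train$label == cl) - floor(n_cl * 0.7)), 1)
  }
  expect_error(split_dataset(ser, 1.0), "strictly between")
})

test_that("stratification errors when a class has fewer than 2 samples", {
  v <- array(rnorm(3 * 1 * 4), dim = c(3, 1, 4, 1))
  labels <- structure(list(labels = matrix(c(0L, 0L, 0L, 2L), 4, 1),
                           levels = c(a = 0L, b = 1L, c = 2L)),
                      class = "label_raster")
  ser <- build_series(tiny_index_stack(v), labels)
  expect_error(split_dataset(ser, 0.8), "fewer than 2")
})

test_that("standardization is train-fitted: train moments 0/1, constant channels pass through", {
  set.seed(9)
  v <- array(rnorm(5 * 3 * 60), dim = c(5, 3, 60, 1))
  v[, 2, , ] <- 7                            # constant channel
  labels <- structure(list(labels = matrix(rep(0:1, each = 30), 60, 1),
                           levels = c(a = 0L, b = 1L, c = 2L)),
                      class = "label_raster")
  ser <- build_series(tiny_index_stack(v), labels)
  sp <- split_dataset(ser, 0.8, seed = 2)
  std <- standardize_series(sp$train, sp$test)

  expect_equal(mean(std$train$x[, , 1]), 0, tolerance = 1e-10)
  expect_equal(sd(as.vector(std$train$x[, , 1])), 1, tolerance = 1e-10)
  # sd-zero fallback: shifted but unscaled
  expect_identical(std$scale[[2]], 1)
  expect_true(all(std$train$x[, , 2] == 0))
  # test-set moments inherit train scaling, need not be exactly 0/1
  expect_false(isTRUE(all.equal(mean(std$test$x[, , 1]), 0, tolerance = 1e-12)))
})
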