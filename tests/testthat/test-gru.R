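zero_weights <- function(d = 3, h = 4, head = 2, k = 3) {
  list(Wxr = matrix(0, d, h), Wxz = matrix(0, d, h), Wxh = matrix(0, d, h),
       Whr = matrix(0, h, h), Whz = matrix(0, h, h), Whh = matrix(0, h, h),
       br = numeric(h), bz = numeric(h), bh = numeric(h),
       W1 = matrix(0, h, head), b1 = numeric(head),
       W2 = matrix(0, head, k), b2 = numeric(k))
}

test_that("with all-zero weights one step halves the previous hidden state", {
  w <- zero_weights()
  x <- matrix(rnorm(3), 1, 3)
  h_prev <- matrix(c(0.4, -0.6, 1, 0.1), 1, 4)
  expect_equal(gru_cell_step(x, h_prev, w), 0.5 * h_prev)
})

test_that("a saturated-negative reset bias discards history from the candidate", {
  set.seed(2)
  cfg <- gru_config(input_size = 3, hidden_size = 4, n_classes = 3,
                    head_size = 2, seed = 2)
  w <- gru_init(cfg)
  w$br <- rep(-1e4, 4)                      # reset gate forced to 0
  x <- matrix(rnorm(3), 1, 3)
  h_prev <- matrix(rnorm(4), 1, 4)
  st <- ricegru:::gru_cell_full(x, h_prev, w)
  expect_equal(max(abs(st$r)), 0)
  # candidate then ignores h_prev entirely
  expect_equal(as.vector(st$h_tilde),
               as.vector(tanh(x %*% w$Wxh + matrix(w$bh, 1, 4))))
  st2 <- ricegru:::gru_cell_full(x, matrix(rnorm(4), 1, 4), w)
  expect_equal(st$h_tilde, st2$h_tilde)
})

test_that("gates lie strictly in (0,1), candidate in (-1,1), hidden state stays bounded", {
  for (seed in 1:5) {
    inst <- random_gru_instance(seed)
    h <- matrix(runif(2 * 4, -1, 1), 2, 4)
    for (t in 1:5) {
      st <- ricegru:::gru_cell_full(matrix(inst$x[, t, ], 2, 3), h, inst$w)
      expect_true(all(st$r > 0 & st$r < 1))
      expect_true(all(st$z > 0 & st$z < 1))
      expect_true(all(st$h_tilde > -1 & st$h_tilde < 1))
      expect_lte(max(abs(st$h)), 1)          # convex combination bound
      h <- st$h
    }
  }
})

test_that("forward pass yields normalized, deterministic probabilities", {
  inst <- random_gru_instance(11)
  model <- list(weights = inst$w, config = inst$cfg)
  p <- gru_forward(model, inst$x)
  expect_equal(unname(rowSums(p)), rep(1, 2), tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_identical(p, gru_forward(model, inst$x))

  # identical sequences give identical outputs
  x2 <- inst$x
  x2[2, , ] <- x2[1, , ]
  p2 <- gru_forward(model, x2)
  expect_equal(p2[1, ], p2[2, ])

  # zero-initialized dense head: uniform class probabilities
  wz <- inst$w
  wz$W1[] <- 0; wz$b1[] <- 0; wz$W2[] <- 0; wz$b2[] <- 0
  pz <- gru_forward(list(weights = wz, config = inst$cfg), inst$x)
  expect_equal(unname(pz), matrix(1 / 3, 2, 3), tolerance = 1e-12)

  expect_error(gru_forward(model, array(0, dim = c(1, 0, 3))), "T >= 1")
})

test_that("analytic gradients match central finite differences on random small instances", {
  for (seed in 1:5) {
    inst <- random_gru_instance(seed, d = 3, h = 4, nt = 5)
    analytic <- ricegru:::gru_loss_grad(inst$w, inst$x, inst$y)$grad
    numeric_ <- fd_gradient(inst$w, inst$x, inst$y)
    expect_lt(max_rel_grad_err(analytic, numeric_), 1e-4)
  }
})

test_that("parameter count matches the closed form", {
  expect_identical(gru_param_count(8, 256, 128, 3),
                   3 * (8 * 256 + 256 * 256 + 256) + (256 * 128 + 128) +
                     (128 * 3 + 3))
  cfg <- gru_config(input_size = 8, hidden_size = 256)
  w <- gru_init(cfg)
  expect_identical(sum(vapply(w, length, integer(1))),
                   as.integer(gru_param_count(8, 256, 128, 3)))
})

two_class_toy <- function(n_per = 30, nt = 6, seed = 1) {
  # class separates on the mean level of channel 1
  set.seed(seed)
  n <- 2 * n_per
  x <- array(rnorm(n * nt * 2, sd = 0.3), dim = c(n, nt, 2))
  x[seq_len(n_per), , 1] <- x[seq_len(n_per), , 1] + 1.5
  structure(list(x = x, label = rep(c(1L, 2L), each = n_per),
                 row = seq_len(n), col = rep(1L, n),
                 gap_fraction = numeric(n), dates = seq_len(nt),
                 indices = c("a", "b"), n_dropped = 0L,
                 grid_dim = c(n, 1L)),
            class = "index_series_set")
}

test_that("training is deterministic given the seed and a zero step leaves weights unchanged", {
  tr <- two_class_toy(seed = 1)
  te <- two_class_toy(seed = 2)
  cfg <- gru_config(input_size = 2, hidden_size = 6, batch_size = 8,
                    n_classes = 2, max_epochs = 3, patience = 3,
                    learning_rate = 0.01, seed = 4)
  m1 <- train_gru(tr, te, cfg)
  m2 <- train_gru(tr, te, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history[setdiff(names(m1$history), "seconds")],
                   m2$history[setdiff(names(m2$history), "seconds")])

  cfg0 <- gru_config(input_size = 2, hidden_size = 6, batch_size = 8,
                     n_classes = 2, max_epochs = 2, patience = 2,
                     learning_rate = 0, seed = 4)
  m0 <- train_gru(tr, te, cfg0)
  w_init <- ricegru:::local_seed(cfg0$seed, {
    gru_init(cfg0, seed = stats::runif(1, 1, 2^30))
  })
  expect_identical(m0$weights, w_init)
})

test_that("training reduces loss and learns a separable toy problem", {
  tr <- two_class_toy(n_per = 40, seed = 3)
  te <- two_class_toy(n_per = 20, seed = 4)
  cfg <- gru_config(input_size = 2, hidden_size = 8, batch_size = 8,
                    n_classes = 2, max_epochs = 15, patience = 15,
                    learning_rate = 0.01, seed = 7)
  m <- train_gru(tr, te, cfg)
  h <- m$history
  expect_lte(h$train_loss[nrow(h)], h$train_loss[1])
  expect_gte(max(h$test_accuracy), 0.95)
})

test_that("prediction maps carry no-data 255 on masked pixels and break ties low", {
  tr <- two_class_toy(seed = 5)
  te <- two_class_toy(seed = 6)
  cfg <- gru_config(input_size = 2, hidden_size = 4, batch_size = 8,
                    n_classes = 2, max_epochs = 1, patience = 1,
                    learning_rate = 0.01, seed = 1)
  m <- train_gru(tr, te, cfg)
  sub <- ricegru:::series_subset(te, 1:10)
  sub$grid_dim <- c(60L, 1L)
  map <- predict_map(m, sub)
  expect_identical(dim(map), c(60L, 1L))
  expect_identical(sum(map != 255L), 10L)
  expect_true(all(map[11:60, 1] == 255L))
  expect_true(all(map[1:10, 1] %in% c(1L, 2L)))

  # argmax tie on equal scores resolves to the lowest class index
  wz <- m$weights
  wz$W2[] <- 0; wz$b2[] <- 0                 # all scores equal -> tie
  mz <- m; mz$weights <- wz
  expect_true(all(predict_series(mz, sub) == m$classes[1]))
})

test_that("shape and configuration errors are caught", {
  inst <- random_gru_instance(1)
  expect_error(gru_cell_step(matrix(0, 1, 5), matrix(0, 1, 4), inst$w),
               "5 columns")
  expect_error(gru_cell_step(matrix(0, 1, 3), matrix(0, 1, 7), inst$w),
               "hidden size")
  model <- list(weights = inst$w, config = inst$cfg)
  expect_error(gru_forward(model, array(0, dim = c(1, 5, 9))), "expects 3")
  tr <- two_class_toy()
  expect_error(train_gru(tr, tr, gru_config(input_size = 8, n_classes = 2)),
               "input_size")
  expect_error(train_gru(tr, tr, gru_config(input_size = 2, n_classes = 3)),
               "n_classes")
})
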