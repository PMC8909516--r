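test_that("confusion counts are oriented predicted-by-reference and transpose under swap", {
  y_true <- c(0, 0, 1, 1, 2, 2, 2)
  y_pred <- c(0, 1, 1, 1, 2, 0, 2)
  cm <- confusion(y_true, y_pred, 3)
  expect_identical(sum(cm), 7L)
  expect_identical(cm[2, 1], 1L)              # predicted 1, reference 0
  expect_identical(as.integer(rowSums(cm)),
                   vapply(0:2, function(cl) sum(y_pred == cl), integer(1)))
  expect_identical(as.integer(colSums(cm)),
                   vapply(0:2, function(cl) sum(y_true == cl), integer(1)))

  swapped <- confusion(y_pred, y_true, 3)
  expect_identical(unclass(unname(swapped)), t(unclass(unname(cm))))

  ident <- confusion(y_true, y_true, 3)
  expect_identical(sum(ident) - sum(diag(ident)), 0L)

  expect_error(confusion(c(0, 3), c(0, 1), 3), "outside")
  expect_error(confusion(c(0, 1), c(0), 2), "length")
})

test_that("metrics agree with a brute-force pair-counting oracle on random labels", {
  set.seed(10)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    n <- sample(50:1000, 1)
    y_true <- sample(0:(k - 1), n, replace = TRUE)
    y_pred <- ifelse(runif(n) < 0.7, y_true, sample(0:(k - 1), n, replace = TRUE))
    cm <- confusion(y_true, y_pred, k)
    oracle <- oracle_metrics(y_true, y_pred, k)
    expect_equal(unclass(unname(cm)), oracle$cm, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(overall_accuracy(cm), oracle$overall, tolerance = 1e-12)
    expect_equal(kappa_coef(cm), oracle$kappa, tolerance = 1e-12)
    for (i in seq_len(k))
      expect_equal(class_metrics(cm, i), oracle$per_class[[i]],
                   tolerance = 1e-12)
  }
})

test_that("overall accuracy is permutation-invariant and trace-based", {
  set.seed(4)
  y_true <- sample(0:2, 300, replace = TRUE)
  y_pred <- sample(0:2, 300, replace = TRUE)
  oa <- overall_accuracy(confusion(y_true, y_pred, 3))
  expect_equal(oa, mean(y_true == y_pred), tolerance = 1e-15)
  perm <- c(2L, 0L, 1L)
  oa_p <- overall_accuracy(confusion(perm[y_true + 1], perm[y_pred + 1], 3))
  expect_equal(oa_p, oa, tolerance = 1e-15)

  uniform <- as_confusion(matrix(5, 2, 2))
  expect_equal(overall_accuracy(uniform), 0.5)
})

test_that("kappa is 1 for perfect agreement, 0 under independence, never above 1", {
  perfect <- as_confusion(diag(c(10, 20, 5)))
  expect_equal(kappa_coef(perfect), 1)

  # product matrix: counts proportional to row x column marginals
  p_pred <- c(0.2, 0.5, 0.3)
  p_ref <- c(0.6, 0.3, 0.1)
  prod_cm <- as_confusion(outer(p_pred, p_ref) * 1000)
  expect_equal(kappa_coef(prod_cm), 0, tolerance = 1e-12)

  set.seed(2)
  for (rep in 1:20) {
    cm <- as_confusion(matrix(rpois(9, 20) + 1, 3, 3))
    expect_lte(kappa_coef(cm), 1)
  }

  # degenerate single-class case
  single <- as_confusion(matrix(c(7, 0, 0, 0), 2, 2))
  expect_equal(kappa_coef(single), 1)
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(round(100 * f1_score(0.9043, 0.9066), 2), 90.54)
  expect_equal(f1_score(1, 1), 1)
  expect_true(is.na(f1_score(0, 0)))
  expect_true(is.na(f1_score(NA, 0.5)))
})

test_that("perfect diagonal gives unit precision/recall/F1 for every class", {
  cm <- as_confusion(diag(c(3, 4, 5)))
  for (i in 1:3) {
    m <- class_metrics(cm, i)
    expect_equal(unname(m[c("precision", "recall", "f1")]), rep(1, 3))
  }
})

test_that("undefined ratios on empty classes are NA, never zero", {
  cm <- as_confusion(matrix(c(5, 3, 0, 0), 2, 2, byrow = TRUE))
  # class 2 never predicted: precision undefined
  m2 <- class_metrics(cm, 2)
  expect_true(is.na(m2[["precision"]]))
  up <- users_producers(cm)
  expect_true(is.na(up$users[2]))
  expect_false(is.na(up$producers[1]))
})

test_that("published 2020/2021 validation tables reproduce their printed metrics", {
  t3 <- validation_table_2020()
  expect_equal(round(100 * overall_accuracy(t3), 2), 92.46)
  expect_equal(round(100 * kappa_coef(t3), 2), 82.96)
  up3 <- users_producers(t3)
  expect_equal(round(100 * up3$users, 2), c(90.37, 93.46))
  expect_equal(round(100 * up3$producers, 2), c(86.87, 95.30))

  t4 <- validation_table_2021()
  expect_equal(round(100 * overall_accuracy(t4), 2), 91.22)
  expect_equal(round(100 * kappa_coef(t4), 2), 77.01)
  up4 <- users_producers(t4)
  expect_equal(round(100 * up4$users, 2), c(80.89, 94.91))
  expect_equal(round(100 * up4$producers, 2), c(85.05, 93.28))
})

test_that("metric reports print and export without loss", {
  t3 <- validation_table_2020()
  rep3 <- metric_report(t3)
  expect_output(print(rep3), "Overall Accuracy 92.46%", fixed = TRUE)
  expect_output(print(rep3), "Kappa 82.96%", fixed = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep3, path)
  back <- read.csv(path)
  expect_equal(back$overall_accuracy[1], rep3$overall_accuracy)
  expect_equal(back$kappa[1], rep3$kappa)
})
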