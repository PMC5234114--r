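# a linearly separable 4-class toy cohort: feature `sep` encodes the class,
# the remaining columns are pure noise
make_separable <- function(n_per_class = 5, n_noise = 10, gap = 1, seed = 101) {
  withr::with_seed(seed, {
    y <- rep(severity_levels, each = n_per_class)
    n <- length(y)
    sep <- rep(seq_along(severity_levels), each = n_per_class) * gap +
      runif(n, 0, gap / 10)
    noise <- matrix(rnorm(n * n_noise), n)
    colnames(noise) <- sprintf("noise_%02d", seq_len(n_noise))
    tibble::as_tibble(as.data.frame(noise)) |>
      dplyr::mutate(sep = sep, severity = y, .before = 1)
  })
}

test_that("AHI maps to the clinical severity bands", {
  expect_identical(
    as.character(ahi_to_severity(c(0, 4, 4.5, 5, 14, 14.9, 15, 29, 30, 100))),
    c("normal", "normal", "normal", "mild", "mild", "mild",
      "moderate", "moderate", "severe", "severe")
  )
  expect_error(ahi_to_severity(-1), "non-negative")
  expect_error(ahi_to_severity(NA_real_), "non-negative")
})

test_that("metrics match hand-computed values on an arbitrary matrix", {
  cm <- confusion_matrix(
    truth = rep(severity_levels, c(3, 4, 2, 3)),
    predicted = c("normal", "normal", "mild",
                  "mild", "mild", "moderate", "normal",
                  "moderate", "severe",
                  "severe", "severe", "severe")
  )
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, (2 + 2 + 1 + 3) / 12)
  # hand: normal row 3, col 3 (2 tp); fp = 1 from mild
  expect_equal(m$per_class$tp_rate[1], 2 / 3)
  expect_equal(m$per_class$precision[1], 2 / 3)
  expect_equal(m$per_class$fp_rate[1], 1 / 9)
  # weighted recall equals accuracy (class-size weights)
  expect_equal(m$weighted$recall, m$accuracy)
  # F = harmonic mean of P and R
  expect_equal(
    m$per_class$f_measure,
    2 * m$per_class$precision * m$per_class$recall /
      pmax(m$per_class$precision + m$per_class$recall, 1e-12)
  )
})

test_that("zero-denominator metric cells report 0 with a flag", {
  cm <- matrix(c(5, 0, 0, 0,
                 2, 0, 0, 0,
                 0, 0, 3, 0,
                 0, 0, 0, 4), 4, 4, byrow = TRUE,
               dimnames = list(severity_levels, severity_levels))
  m <- compute_metrics(cm)
  expect_true(m$zero_denominator)
  expect_equal(m$per_class$precision[2], 0)  # mild never predicted
  expect_equal(m$per_class$tp_rate[2], 0)
  expect_true(all(m$per_class$precision >= 0 & m$per_class$precision <= 1))
})

test_that("a diagonal confusion matrix gives perfect metrics", {
  cm <- diag(c(5L, 6L, 7L, 8L))
  dimnames(cm) <- list(severity_levels, severity_levels)
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_class$f_measure == 1))
  expect_true(all(m$per_class$fp_rate == 0))
  b <- binarize_confusion(cm)
  expect_equal(b$sensitivity, 1)
  expect_equal(b$specificity, 1)
  expect_equal(b$accuracy, 1)
})

test_that("feature selection finds a constructed separating feature", {
  d <- make_separable()
  sel <- select_features(d, k = 5, folds = 5, seed = 1)
  expect_identical(sel$ranked$feature[1], "sep")
  expect_true("sep" %in% sel$selected)
  expect_gte(sel$cv_score, 0.9)
  expect_lte(length(sel$selected), sel$k)
  expect_error(select_features(d, k = 0), "k")
})

test_that("selection on pure noise scores near chance", {
  # enough subjects that the winner's-curse bias of searching a handful of
  # noise features stays inside the binomial envelope around chance
  withr::with_seed(37, {
    n <- 100
    d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 6), n)))
    names(d) <- sprintf("f%02d", 1:6)
    d$severity <- rep(severity_levels, each = n / 4)
    sel <- select_features(d, k = 6, folds = 5, seed = 2)
    sigma <- sqrt(0.25 * 0.75 / n)
    expect_lte(sel$cv_score, 0.25 + 3 * sigma)
  })
})

test_that("k larger than the feature count is clamped", {
  d <- make_separable(n_noise = 3)
  sel <- select_features(d, k = 500, folds = 5, seed = 1)
  expect_identical(sel$k, 4L)  # sep + 3 noise columns
})

test_that("the linear SVM separates separable data and stores its scaler", {
  d <- make_separable()
  fit <- train_svm(d, features = "sep")
  expect_identical(as.character(predict(fit, d)), d$severity)

  # rescaling all inputs leaves predictions unchanged (scaler absorbs it)
  d2 <- d
  d2$sep <- d2$sep * 1000
  fit2 <- train_svm(d2, features = "sep")
  expect_identical(as.character(predict(fit2, d2)),
                   as.character(predict(fit, d)))

  one_class <- dplyr::filter(d, .data$severity == "mild")
  expect_error(train_svm(one_class), "2 classes")
})

test_that("LOOCV predicts every subject exactly once and nails wide margins", {
  d <- make_separable(gap = 5)
  ev <- loocv_evaluate(d, k = 3, folds = 5, seed = 1)
  expect_equal(sum(ev$confusion), nrow(d))
  expect_equal(ev$metrics$accuracy, 1)
  expect_true(all(ev$confusion == diag(c(5, 5, 5, 5))))
  expect_equal(nrow(ev$predictions), nrow(d))
})

test_that("LOOCV with all-constant features falls back to the majority class", {
  d <- tibble::tibble(
    a = 0, b = 0,
    severity = rep(c("normal", "mild"), c(4, 8))
  )
  ev <- suppressWarnings(
    loocv_evaluate(d, features = c("a", "b"), folds = 2, seed = 1)
  )
  expect_true(all(ev$predictions$predicted == "mild"))
})

test_that("nested LOOCV is leakage-free against an identifying feature", {
  d <- make_separable(n_per_class = 3, n_noise = 4)
  base <- loocv_evaluate(d, k = 3, folds = 2, seed = 5, nested = TRUE)
  # poison only the held-out subject with an identifying column
  d2 <- d
  d2$leak <- 0
  d2$leak[1] <- 1e6
  poisoned <- loocv_evaluate(d2, k = 3, folds = 2, seed = 5, nested = TRUE)
  expect_identical(poisoned$predictions$predicted[1],
                   base$predictions$predicted[1])
})

test_that("selection + training + LOOCV are deterministic under a seed", {
  d <- make_separable(n_noise = 6)
  e1 <- loocv_evaluate(d, k = 4, folds = 5, seed = 9)
  e2 <- loocv_evaluate(d, k = 4, folds = 5, seed = 9)
  expect_identical(e1$predictions, e2$predictions)
  expect_identical(e1$selection$selected, e2$selection$selected)
})

test_that("binary collapse counts any non-normal prediction as positive", {
  cm <- matrix(c(10, 1, 1, 0,
                 2, 5, 1, 0,
                 1, 1, 6, 1,
                 0, 0, 2, 9), 4, 4, byrow = TRUE,
               dimnames = list(severity_levels, severity_levels))
  b <- binarize_confusion(cm)
  tp <- 5 + 1 + 0 + 1 + 6 + 1 + 0 + 2 + 9
  fn <- 2 + 1 + 0
  tn <- 10
  fp <- 1 + 1 + 0
  expect_equal(b$sensitivity, tp / (tp + fn))
  expect_equal(b$specificity, tn / (tn + fp))
  expect_equal(b$accuracy, (tp + tn) / sum(cm))
})

test_that("tidy and glance methods return well-formed tibbles", {
  cm <- confusion_matrix(
    rep(severity_levels, each = 3),
    rep(severity_levels, each = 3)
  )
  m <- compute_metrics(cm)
  expect_s3_class(tidy(m), "tbl_df")
  expect_named(
    glance(m),
    c("accuracy", "weighted_tp_rate", "weighted_fp_rate",
      "weighted_precision", "weighted_recall", "weighted_f_measure")
  )
  td <- tidy(cm)
  expect_equal(sum(td$count), 12)
})
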