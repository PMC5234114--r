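#' Severity class order used throughout the package
#' @export
severity_levels <- c("normal", "mild", "moderate", "severe")

#' Map AHI to OSA severity class
#'
#' Standard clinical bands: normal below 5 events/hour, mild 5 to below 15,
#' moderate 15 to below 30, severe 30 and above. Implemented as half-open
#' intervals so non-integer AHI values are covered (4.5 is mild).
#'
#' @param ahi Numeric vector of apnea-hypopnea indices (events/hour, >= 0).
#' @return Factor with levels `normal < mild < moderate < severe`.
#' @export
#' @examples
#' ahi_to_severity(c(0, 4.5, 14, 30))
ahi_to_severity <- function(ahi) {
  if (any(is.na(ahi)) || any(ahi < 0)) {
    rlang::abort("AHI must be non-negative and non-missing.")
  }
  cut(ahi, breaks = c(0, 5, 15, 30, Inf), right = FALSE,
      labels = severity_levels, ordered_result = FALSE)
}

#' Build a confusion matrix with the fixed severity class order
#'
#' @param truth,predicted Vectors of class labels (character or factor).
#' @param levels Class order (default [severity_levels]).
#' @return An object of class `osa_confusion`: an integer matrix, rows = true
#'   class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, levels = severity_levels) {
  t_f <- factor(as.character(truth), levels = levels)
  p_f <- factor(as.character(predicted), levels = levels)
  if (anyNA(t_f) || anyNA(p_f)) {
    rlang::abort("Labels outside the expected class set.")
  }
  cm <- unclass(table(truth = t_f, predicted = p_f))
  structure(cm, class = c("osa_confusion", "matrix"))
}

#' @export
print.osa_confusion <- function(x, ...) {
  cat("<osa_confusion> rows = truth, columns = predicted\n")
  print(unclass(x))
  invisible(x)
}

# ---- internal CV machinery -------------------------------------------------

# stratified fold assignment, deterministic under seed
.assign_folds <- function(y, folds, seed) {
  withr::with_seed(as.integer(seed), {
    id <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
}

# min-max scaling helpers; constant features map to 0
.fit_scaler <- function(X) {
  list(min = apply(X, 2L, min), range = apply(X, 2L, function(v) diff(range(v))))
}
.apply_scaler <- function(X, sc) {
  rng <- ifelse(sc$range > 0, sc$range, 1)
  out <- sweep(sweep(X, 2L, sc$min), 2L, rng, "/")
  out[, sc$range == 0] <- 0
  out
}

# linear-SVM CV accuracy of a feature subset; folds precomputed
.cv_accuracy <- function(X, y, fold_id, C = 100) {
  n_ok <- 0L
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- droplevels(y[tr])
    Xte <- X[!tr, , drop = FALSE]
    if (nlevels(ytr) < 2L) {
      pred <- factor(rep(levels(ytr)[1L], nrow(Xte)), levels = levels(y))
    } else {
      sc <- .fit_scaler(Xtr)
      fit <- e1071::svm(.apply_scaler(Xtr, sc), ytr, kernel = "linear",
                        cost = C, scale = FALSE)
      pred <- stats::predict(fit, .apply_scaler(Xte, sc))
    }
    n_ok <- n_ok + sum(as.character(pred) == as.character(y[!tr]))
  }
  n_ok / length(y)
}

# split a feature table into label vector + numeric feature matrix
.split_features <- function(data, outcome = "severity",
                            exclude = c("subject_id", "ahi")) {
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) {
    rlang::abort(sprintf("Column `%s` not found.", outcome))
  }
  y <- factor(as.character(data[[outcome]]),
              levels = intersect(severity_levels, unique(as.character(data[[outcome]]))))
  feat_cols <- setdiff(names(data), c(outcome, exclude))
  feat_cols <- feat_cols[vapply(data[feat_cols], is.numeric, logical(1))]
  X <- as.matrix(data[feat_cols])
  if (anyNA(X)) rlang::abort("Feature table contains missing values.")
  list(X = X, y = y, features = feat_cols)
}

#' Wrapper feature selection with linear forward search
#'
#' Two-stage wrapper selection, scored throughout by the stratified m-fold
#' cross-validated accuracy of a linear SVM. Stage one ranks every feature by
#' its single-feature CV accuracy. Stage two runs greedy forward selection
#' within the `k` top-ranked features: at each step the feature whose addition
#' maximizes the subset's CV accuracy is added, stopping when no addition
#' strictly improves the score. Ties break toward the lower original feature
#' index, so the procedure is deterministic under a fixed seed.
#'
#' @param data Data frame / tibble with a `severity` column and numeric
#'   feature columns; `subject_id` and `ahi` columns are ignored.
#' @param k Cap on the ranked pool entering forward selection (default 50;
#'   clamped to the number of features).
#' @param folds Cross-validation folds m (default 5).
#' @param seed Integer seed for the stratified fold assignment.
#' @param C Linear-SVM cost parameter (default 100; see Details in [train_svm()]).
#' @param outcome,exclude Column handling, see above.
#'
#' @return An object of class `osa_selection`: `ranked` (tibble of feature,
#'   score, rank), `selected` (ordered character vector), `cv_score`, `k`,
#'   `folds`, `seed`.
#' @export
select_features <- function(data, k = 50, folds = 5, seed = 1L, C = 100,
                            outcome = "severity",
                            exclude = c("subject_id", "ahi")) {
  if (k < 1) rlang::abort("`k` must be >= 1.")
  sp <- .split_features(data, outcome, exclude)
  if (nlevels(sp$y) < 2L) rlang::abort("Need at least 2 classes to select features.")
  if (min(table(sp$y)) < folds) {
    rlang::abort("Each class needs at least `folds` subjects.")
  }
  fold_id <- .assign_folds(sp$y, folds, seed)

  scores <- vapply(
    seq_along(sp$features),
    function(j) .cv_accuracy(sp$X[, j, drop = FALSE], sp$y, fold_id, C),
    numeric(1)
  )
  ord <- order(-scores, seq_along(scores))
  k <- as.integer(min(k, length(sp$features)))
  ranked <- tibble::tibble(
    feature = sp$features[ord], score = scores[ord], rank = seq_along(ord)
  )
  pool <- ord[seq_len(k)]

  selected <- integer(0)
  best <- -Inf
  repeat {
    cand <- setdiff(pool, selected)
    if (length(cand) == 0L) break
    cand_scores <- vapply(
      cand,
      function(j) .cv_accuracy(sp$X[, c(selected, j), drop = FALSE],
                               sp$y, fold_id, C),
      numeric(1)
    )
    pick <- which(cand_scores > best + 1e-12)
    if (length(pick) == 0L) break
    # best score, ties toward the lower original feature index
    top <- cand[pick][order(-cand_scores[pick], cand[pick])][1L]
    selected <- c(selected, top)
    best <- max(cand_scores)
  }
  structure(
    list(
      ranked = ranked,
      selected = sp$features[selected],
      cv_score = if (is.finite(best)) best else NA_real_,
      k = k, folds = folds, seed = seed
    ),
    class = "osa_selection"
  )
}

#' @export
print.osa_selection <- function(x, ...) {
  cat(sprintf(
    "<osa_selection> %d feature(s) selected from top-%d pool, CV accuracy %.3f\n",
    length(x$selected), x$k, x$cv_score
  ))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Train a linear SVM severity classifier
#'
#' Features are min-max scaled to \[0, 1\] using training-data ranges (the
#' scaler is stored with the model, so rescaled inputs give identical
#' predictions), then a linear-kernel SVM with pairwise one-vs-one multiclass
#' voting is fit.
#'
#' @param data Feature table with `severity` plus numeric feature columns.
#' @param features Character vector of feature columns to use (default: all).
#' @param C Cost parameter (default 100). With min-max scaled features a near-hard-margin cost is needed: at small sample sizes a low cost leaves every margin constraint at bound, the pairwise decision rules collapse to majority voting, and predictions follow class imbalance instead of the features.
#' @param outcome,exclude Column handling as in [select_features()].
#' @return An object of class `osa_svm`.
#' @export
train_svm <- function(data, features = NULL, C = 100, outcome = "severity",
                      exclude = c("subject_id", "ahi")) {
  sp <- .split_features(data, outcome, exclude)
  if (nlevels(sp$y) < 2L) rlang::abort("Need at least 2 classes to train.")
  features <- features %||% sp$features
  missing <- setdiff(features, sp$features)
  if (length(missing)) {
    rlang::abort(sprintf("Unknown feature(s): %s", paste(missing, collapse = ", ")))
  }
  X <- sp$X[, features, drop = FALSE]
  sc <- .fit_scaler(X)
  fit <- e1071::svm(.apply_scaler(X, sc), sp$y, kernel = "linear", cost = C,
                    scale = FALSE)
  structure(
    list(svm = fit, features = features, scaler = sc, C = C,
         classes = levels(sp$y)),
    class = "osa_svm"
  )
}

#' @export
predict.osa_svm <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[object$features])
  stats::predict(object$svm, .apply_scaler(X, object$scaler))
}

#' Leave-one-out cross-validation of the severity model
#'
#' For each subject, trains on the remaining n - 1 subjects and predicts the
#' held-out subject; predictions are accumulated into a 4x4 confusion matrix.
#' Scaling and SVM training always use only the training fold. Feature
#' selection is, by default, performed once on the full table and the
#' resulting subset reused in every fold (the workflow in which a published
#' subset precedes classification); `nested = TRUE` instead reruns selection
#' inside every fold for a strictly leakage-free estimate.
#'
#' @param data Feature table with `severity` plus numeric feature columns.
#' @param k,folds,seed,C Selection and SVM parameters, see
#'   [select_features()].
#' @param nested Rerun feature selection inside each LOOCV fold
#'   (default FALSE).
#' @param features Optional fixed feature subset; skips selection entirely.
#' @param outcome,exclude Column handling as in [select_features()].
#'
#' @return An object of class `osa_eval`: `confusion` (`osa_confusion`),
#'   `predictions` (tibble: subject, truth, predicted), `selection` (the
#'   global `osa_selection`, or NULL when `features` was given or `nested`),
#'   `metrics` ([compute_metrics()] report), `binary`
#'   ([binarize_confusion()] report), `config`.
#' @export
loocv_evaluate <- function(data, k = 50, folds = 5, seed = 1L, C = 100,
                           nested = FALSE, features = NULL,
                           outcome = "severity",
                           exclude = c("subject_id", "ahi")) {
  data <- as.data.frame(data)
  sp <- .split_features(data, outcome, exclude)
  n <- nrow(data)
  if (n < nlevels(sp$y) + 1L) {
    rlang::abort("Need at least one more subject than classes.")
  }
  selection <- NULL
  if (is.null(features) && !nested) {
    selection <- select_features(data, k = k, folds = folds, seed = seed,
                                 C = C, outcome = outcome, exclude = exclude)
    features <- selection$selected
  }
  preds <- character(n)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    if (nested && is.null(selection)) {
      sel_i <- select_features(train, k = k, folds = folds, seed = seed,
                               C = C, outcome = outcome, exclude = exclude)
      feats_i <- sel_i$selected
    } else {
      feats_i <- features
    }
    y_tr <- factor(as.character(train[[outcome]]), levels = severity_levels)
    if (nlevels(droplevels(y_tr)) < nlevels(droplevels(factor(sp$y)))) {
      rlang::warn(sprintf("Fold %d training set is missing a class.", i))
    }
    fit <- train_svm(train, features = feats_i, C = C, outcome = outcome,
                     exclude = exclude)
    preds[i] <- as.character(predict(fit, data[i, , drop = FALSE]))
  }
  truth <- as.character(data[[outcome]])
  cm <- confusion_matrix(truth, preds,
                         levels = intersect(severity_levels, unique(truth)))
  ids <- if ("subject_id" %in% names(data)) data$subject_id else seq_len(n)
  structure(
    list(
      confusion = cm,
      predictions = tibble::tibble(subject_id = ids, truth = truth,
                                   predicted = preds),
      selection = selection,
      metrics = compute_metrics(cm),
      binary = if (all(dim(cm) == c(4L, 4L))) binarize_confusion(cm) else NULL,
      config = list(k = k, folds = folds, seed = seed, C = C, nested = nested)
    ),
    class = "osa_eval"
  )
}

#' @export
print.osa_eval <- function(x, ...) {
  cat(sprintf(
    "<osa_eval> LOOCV over %d subjects: accuracy %.2f%%\n",
    sum(x$confusion), 100 * x$metrics$accuracy
  ))
  print(x$confusion)
  invisible(x)
}

#' Per-class and overall metrics from a confusion matrix
#'
#' True-positive rate (recall), false-positive rate, precision and F-measure
#' per class, overall accuracy (trace over total), and class-size-weighted
#' averages. Cells with a zero denominator (empty class or never-predicted
#' class) are reported as 0 and flagged.
#'
#' @param cm An `osa_confusion` or plain square count matrix.
#' @return An object of class `osa_metrics`: `per_class` tibble, `accuracy`,
#'   `weighted` (one-row tibble), `zero_denominator` flag.
#' @export
compute_metrics <- function(cm) {
  m <- unclass(as.matrix(cm))
  total <- sum(m)
  if (total <= 0) rlang::abort("Confusion matrix is empty.")
  classes <- rownames(m) %||% as.character(seq_len(nrow(m)))
  rows <- rowSums(m)
  cols <- colSums(m)
  tp <- diag(m)
  flag <- FALSE
  safe_div <- function(num, den) {
    bad <- den == 0
    if (any(bad)) flag <<- TRUE
    out <- ifelse(bad, 0, num / ifelse(bad, 1, den))
    out
  }
  tp_rate <- unname(safe_div(tp, rows))
  fp_rate <- unname(safe_div(cols - tp, total - rows))
  precision <- unname(safe_div(tp, cols))
  f_measure <- safe_div(2 * precision * tp_rate, precision + tp_rate)
  per_class <- tibble::tibble(
    class = classes, tp_rate = tp_rate, fp_rate = fp_rate,
    precision = precision, recall = tp_rate, f_measure = f_measure,
    n = unname(as.integer(rows))
  )
  w <- rows / total
  weighted <- tibble::tibble(
    tp_rate = sum(w * tp_rate), fp_rate = sum(w * fp_rate),
    precision = sum(w * precision), recall = sum(w * tp_rate),
    f_measure = sum(w * f_measure)
  )
  structure(
    list(per_class = per_class, accuracy = sum(tp) / total,
         weighted = weighted, zero_denominator = flag),
    class = "osa_metrics"
  )
}

#' @export
print.osa_metrics <- function(x, ...) {
  cat(sprintf("<osa_metrics> accuracy %.4f\n", x$accuracy))
  print(as.data.frame(x$per_class), digits = 3)
  invisible(x)
}

#' Binary normal-vs-OSA metrics from the 4-class confusion matrix
#'
#' Collapses the four severity classes into normal (negative) versus any OSA
#' (positive: mild, moderate, severe). A prediction counts as positive iff
#' the predicted class is not normal.
#'
#' @param cm A 4x4 `osa_confusion` (class order normal, mild, moderate,
#'   severe).
#' @return A list of class `osa_binary`: `sensitivity`, `specificity`,
#'   `accuracy`, and the 2x2 `counts`.
#' @export
binarize_confusion <- function(cm) {
  m <- unclass(as.matrix(cm))
  stopifnot(all(dim(m) == c(4L, 4L)))
  tn <- m[1L, 1L]
  fp <- sum(m[1L, 2:4])
  fn <- sum(m[2:4, 1L])
  tp <- sum(m[2:4, 2:4])
  counts <- matrix(c(tn, fn, fp, tp), 2L, 2L,
                   dimnames = list(truth = c("normal", "osa"),
                                   predicted = c("normal", "osa")))
  structure(
    list(
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      accuracy = (tp + tn) / sum(m),
      counts = counts
    ),
    class = "osa_binary"
  )
}

#' @export
print.osa_binary <- function(x, ...) {
  cat(sprintf(
    "<osa_binary> sensitivity %.4f, specificity %.4f, accuracy %.4f\n",
    x$sensitivity, x$specificity, x$accuracy
  ))
  invisible(x)
}

# ---- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.osa_metrics <- function(x, ...) x$per_class

#' @export
glance.osa_metrics <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(accuracy = x$accuracy),
    dplyr::rename_with(x$weighted, ~ paste0("weighted_", .x))
  )
}

#' @export
tidy.osa_eval <- function(x, ...) tidy(x$metrics)

#' @export
glance.osa_eval <- function(x, ...) {
  out <- glance(x$metrics)
  if (!is.null(x$binary)) {
    out <- dplyr::bind_cols(out, tibble::tibble(
      binary_sensitivity = x$binary$sensitivity,
      binary_specificity = x$binary$specificity,
      binary_accuracy = x$binary$accuracy
    ))
  }
  out
}

#' @export
tidy.osa_selection <- function(x, ...) {
  dplyr::mutate(x$ranked, selected = .data$feature %in% x$selected)
}

#' @export
tidy.osa_confusion <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE)) |>
    dplyr::rename(count = "Freq")
}
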