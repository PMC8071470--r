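#' Confusion matrix metrics
#'
#' @param tp,fp,tn,fn Non-negative counts. `tp + fn` and `tn + fp` must be
#'   positive so that sensitivity and specificity are defined.
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || any(counts < 0)) {
    stop_gsreg("confusion counts must be non-negative", "gsreg_input_error")
  }
  if (tp + fn <= 0 || tn + fp <= 0) {
    stop_gsreg("undefined metrics: need tp+fn > 0 and tn+fp > 0", "gsreg_input_error")
  }
  tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / sum(counts)
  )
}

#' Repeated cross-validated SVM classification of functionome patterns
#'
#' Classifies samples case vs control from their GSR index profiles with a
#' support vector machine (radial basis kernel, default bandwidth heuristic
#' and unit cost) under stratified k-fold cross-validation repeated with
#' distinct seeded shuffles. Folds are stratified by class so that strongly
#' unbalanced cohorts still yield well-defined folds. Per repeat, the
#' out-of-fold predictions are pooled into one confusion matrix, giving one
#' sensitivity/specificity/accuracy value per repeat; the area under the
#' ROC curve is computed per repeat from the pooled decision values and
#' then averaged. Features enter as-is: GSR indices already live in
#' \[0, 1\], so no further scaling is applied.
#'
#' @param f A [build_functionome()] result with both classes present.
#' @param n_folds Number of folds (default 5); every class must have at
#'   least this many members.
#' @param n_repeats Number of repeated cross-validations (default 10).
#' @param seed Integer seed; the run is fully reproducible under a fixed
#'   seed.
#' @param kernel kernlab kernel name (default `"rbfdot"`).
#' @param C Soft-margin cost (default 1).
#' @return An object of class `gsr_cv`: list with `repeats` (per-repeat
#'   metric tibble), `summary` (one-row tibble of means and SDs plus mean
#'   AUC), `n_folds`, `n_repeats`, `seed`.
#' @export
cv_classify <- function(f, n_folds = 5, n_repeats = 10, seed = 1,
                        kernel = "rbfdot", C = 1) {
  stopifnot(inherits(f, "functionome"))
  y <- factor(unname(f$group), levels = c("control", "case"))
  if (any(is.na(y)) || length(unique(y)) < 2L) {
    stop_gsreg("both case and control samples are required", "gsreg_input_error")
  }
  class_sizes <- table(y)
  if (any(class_sizes < n_folds)) {
    stop_gsreg(
      sprintf("smallest class has %d samples, fewer than n_folds = %d; reduce the number of folds",
              min(class_sizes), n_folds),
      "gsreg_input_error"
    )
  }
  X <- f$gsr
  reps <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    set.seed(substream_seed(seed, paste0("cv_repeat_", r)))
    folds <- stratified_folds(y, n_folds)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    score <- rep(NA_real_, length(y))
    for (k in seq_len(n_folds)) {
      test_idx <- which(folds == k)
      fit <- fit_svm_fold(X[-test_idx, , drop = FALSE], y[-test_idx], kernel, C)
      out <- predict_svm_fold(fit, X[test_idx, , drop = FALSE], y[-test_idx])
      pred[test_idx] <- out$class
      score[test_idx] <- out$score
    }
    cm <- confusion_metrics(
      tp = sum(pred == "case" & y == "case"),
      fp = sum(pred == "case" & y == "control"),
      tn = sum(pred == "control" & y == "control"),
      fn = sum(pred == "control" & y == "case")
    )
    auc <- as.numeric(pROC::auc(
      pROC::roc(response = y, predictor = score,
                levels = c("control", "case"), direction = "<", quiet = TRUE)
    ))
    mutate(cm, repeat_id = r, auc = auc)
  })
  summary <- tibble(
    sensitivity_mean = mean(reps$sensitivity), sensitivity_sd = sd(reps$sensitivity),
    specificity_mean = mean(reps$specificity), specificity_sd = sd(reps$specificity),
    accuracy_mean = mean(reps$accuracy), accuracy_sd = sd(reps$accuracy),
    auc = mean(reps$auc)
  )
  structure(
    list(repeats = reps[, c("repeat_id", "sensitivity", "specificity", "accuracy", "auc")],
         summary = summary, n_folds = n_folds, n_repeats = n_repeats, seed = seed),
    class = "gsr_cv"
  )
}

# balanced fold labels within each class
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

fit_svm_fold <- function(X_train, y_train, kernel, C) {
  fit <- tryCatch(
    kernlab::ksvm(X_train, y_train, type = "C-svc", kernel = kernel, C = C,
                  scaled = FALSE),
    error = function(e) NULL
  )
  # degenerate training data (e.g. constant features) falls back to the
  # majority-class prior with an uninformative decision score
  if (is.null(fit)) {
    return(list(majority = names(which.max(table(y_train)))))
  }
  fit
}

predict_svm_fold <- function(fit, X_test, y_train) {
  if (is.list(fit) && !is.null(fit$majority)) {
    return(list(class = factor(rep(fit$majority, nrow(X_test)), levels = levels(y_train)),
                score = rep(0, nrow(X_test))))
  }
  cls <- kernlab::predict(fit, X_test, type = "response")
  dec <- as.numeric(kernlab::predict(fit, X_test, type = "decision")[, 1L])
  list(class = cls, score = orient_scores(fit, dec, cls))
}

# If the predicted classes disagree with the sign convention of the decision
# values, flip the sign; kernlab does not fix which class gets positive
# scores, and AUC needs a consistent orientation.
orient_scores <- function(fit, dec, cls) {
  if (length(unique(cls)) < 2L || all(!is.finite(dec))) return(dec)
  if (mean(dec[cls == "case"]) < mean(dec[cls == "control"])) -dec else dec
}

#' @export
print.gsr_cv <- function(x, ...) {
  cat(sprintf("<gsr_cv> %d-fold cross-validation, %d repeats (seed %d)\n",
              x$n_folds, x$n_repeats, x$seed))
  print(x$summary)
  invisible(x)
}

#' @describeIn cv_classify Per-repeat metrics, one row per repeat.
#' @param x A `gsr_cv` object.
#' @param ... Ignored.
#' @export
tidy.gsr_cv <- function(x, ...) x$repeats

#' @describeIn cv_classify One-row summary: metric means, SDs across
#'   repeats and mean AUC.
#' @export
glance.gsr_cv <- function(x, ...) {
  mutate(x$summary, n_folds = x$n_folds, n_repeats = x$n_repeats)
}

#' @describeIn cv_classify Dot-and-boxplot of per-repeat sensitivity,
#'   specificity, accuracy and AUC.
#' @param object A `gsr_cv` object.
#' @export
autoplot.gsr_cv <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$repeats, -"repeat_id",
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "value per repeat") +
    ggplot2::theme_minimal()
}
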