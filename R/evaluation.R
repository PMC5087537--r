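# Confusion accounting, the standard binary metrics, cross-validation
# splitters and per-classifier error profiles.

#' Confusion counts for one binary motion classifier
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion_counts: counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_counts")
}

#' Tally confusion counts from binary predictions
#'
#' @param pred,truth Logical vectors (`TRUE` = the classifier's motion).
#' @return A [confusion_counts()] object.
#' @export
tally_confusion <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  confusion_counts(tp = sum(pred & truth), tn = sum(!pred & !truth),
                   fp = sum(pred & !truth), fn = sum(!pred & truth))
}

#' Accuracy, precision and recall from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`. A zero
#' denominator yields `NA` with the affected metric named in the
#' `undefined` attribute — never a silent zero.
#'
#' @param cc A [confusion_counts()] object.
#' @return Named numeric vector `c(accuracy, precision, recall)` (fractions
#'   in `[0, 1]`), with attribute `undefined`.
#' @export
metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  total <- cc$tp + cc$tn + cc$fp + cc$fn
  if (total == 0) stop("metrics: empty confusion counts")
  undefined <- character(0)
  precision <- if (cc$tp + cc$fp == 0) {
    undefined <- c(undefined, "precision"); NA_real_
  } else cc$tp / (cc$tp + cc$fp)
  recall <- if (cc$tp + cc$fn == 0) {
    undefined <- c(undefined, "recall"); NA_real_
  } else cc$tp / (cc$tp + cc$fn)
  out <- c(accuracy = (cc$tp + cc$tn) / total,
           precision = precision, recall = recall)
  attr(out, "undefined") <- undefined
  out
}

#' Random k-fold partition
#'
#' @param n Number of observations.
#' @param k Number of folds (`<= n`).
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return Integer vector of fold assignments in `1..k`, near-equal sizes
#'   (differing by at most one).
#' @export
kfold_split <- function(n, k = 10, seed = 1) {
  if (k > n) stop("kfold_split: k must not exceed n")
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Random holdout split, stratified by label
#'
#' @param labels Vector of class labels (length n).
#' @param fraction Test fraction in (0, 1); default 0.25.
#' @param stratify Preserve per-class proportions (default `TRUE`).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering `1..n`).
#' @export
holdout_split <- function(labels, fraction = 0.25, stratify = TRUE, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  n <- length(labels)
  set.seed(seed)
  if (stratify) {
    test <- unlist(lapply(split(seq_len(n), labels), function(idx) {
      m <- round(fraction * length(idx))
      if (m < 1 || m >= length(idx))
        stop("holdout_split: stratum too small for the requested fraction")
      sample(idx, m)
    }), use.names = FALSE)
  } else {
    test <- sample(n, round(fraction * n))
  }
  list(train = setdiff(seq_len(n), test), test = sort(test))
}

#' Error profile of a motion classifier
#'
#' Distributes a classifier's misclassified events over the true motions
#' and reports which share belongs to the classifier's own motion
#' (`corresponding_motion_error`) versus the other motions
#' (`other_motions_error`); the two percentages sum to 100.
#'
#' @param true_labels True motions of the misclassified events.
#' @param motion The classifier's own motion.
#' @return List with per-motion `counts`, `total`,
#'   `corresponding_motion_error` and `other_motions_error` (percent); or
#'   an empty profile (`total = 0`, flag `empty = TRUE`) when there are no
#'   misclassifications.
#' @export
error_profile <- function(true_labels, motion) {
  stopifnot(motion %in% MOTION_LABELS)
  true_labels <- as.character(true_labels)
  counts <- vapply(MOTION_LABELS, function(m) sum(true_labels == m), integer(1))
  total <- sum(counts)
  if (total == 0)
    return(list(motion = motion, counts = counts, total = 0L,
                corresponding_motion_error = NA_real_,
                other_motions_error = NA_real_, empty = TRUE))
  corr <- 100 * counts[[motion]] / total
  list(motion = motion, counts = counts, total = total,
       corresponding_motion_error = corr,
       other_motions_error = 100 - corr, empty = FALSE)
}

#' Cross-validated evaluation of a classifier bank
#'
#' Trains and tests the one-vs-rest bank under 10-fold or holdout
#' cross-validation and reports, per motion, pooled confusion counts and
#' metrics. For k-fold, each observation is tested exactly once and the
#' per-motion counts are pooled over folds.
#'
#' @param x Feature matrix.
#' @param labels True motion labels.
#' @param backend Classifier backend (see [train_bank()]).
#' @param scheme `"kfold"` or `"holdout"`.
#' @param k Folds for `"kfold"`.
#' @param fraction Test fraction for `"holdout"`.
#' @param hyper,seed Passed to [train_bank()] / the splitters.
#' @return List with `report` (data frame: motion, tp, tn, fp, fn,
#'   accuracy, precision, recall), `predictions` (arbitrated labels on test
#'   data), `truth` and `macro_accuracy` (mean per-motion accuracy).
#' @export
evaluate_bank <- function(x, labels, backend = "svm",
                          scheme = c("kfold", "holdout"),
                          k = 10, fraction = 0.25, hyper = list(), seed = 1) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  x <- as.matrix(x)
  n <- length(labels)
  pred <- rep(NA_character_, n)
  test_idx <- integer(0)
  if (scheme == "kfold") {
    folds <- kfold_split(n, k, seed)
    for (f in seq_len(k)) {
      te <- which(folds == f); tr <- which(folds != f)
      bank <- train_bank(x[tr, , drop = FALSE], labels[tr], backend,
                         hyper = hyper, seed = seed + f)
      pred[te] <- as.character(predict_bank(bank, x[te, , drop = FALSE])$label)
    }
    test_idx <- seq_len(n)
  } else {
    sp <- holdout_split(labels, fraction, seed = seed)
    bank <- train_bank(x[sp$train, , drop = FALSE], labels[sp$train], backend,
                       hyper = hyper, seed = seed)
    pred[sp$test] <- as.character(predict_bank(bank, x[sp$test, , drop = FALSE])$label)
    test_idx <- sp$test
  }
  truth <- labels[test_idx]; phat <- pred[test_idx]
  report <- do.call(rbind, lapply(MOTION_LABELS, function(m) {
    cc <- tally_confusion(phat == m, truth == m)
    mt <- metrics(cc)
    data.frame(motion = m, tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
               accuracy = mt[["accuracy"]], precision = mt[["precision"]],
               recall = mt[["recall"]])
  }))
  list(report = report, predictions = phat, truth = truth,
       macro_accuracy = mean(report$accuracy))
}

#' Published benchmark counts shipped with the package
#'
#' Per-classifier, per-motion 10-fold detection counts (`tp` of `pos_total`
#' actual motions detected, `fp` of `neg_total` other motions flagged) and
#' the misclassification-count table of the SVM bank, from a published
#' five-motion foot-stepping study. Used as worked-example inputs for the
#' metric and error-profile calculators.
#'
#' @return [benchmark_detection_counts()]: data frame with `backend`,
#'   `motion`, `tp`, `pos_total`, `fp`, `neg_total` and derived `fn`, `tn`.
#' @export
benchmark_detection_counts <- function() {
  df <- utils::read.csv(system.file("extdata", "benchmark_detection_counts.csv",
                                    package = "stepdir"))
  df$fn <- df$pos_total - df$tp
  df$tn <- df$neg_total - df$fp
  df
}

#' @rdname benchmark_detection_counts
#' @return [benchmark_error_counts()]: data frame with `scheme`,
#'   `classifier` and one column of misclassified-event counts per true
#'   motion.
#' @export
benchmark_error_counts <- function() {
  utils::read.csv(system.file("extdata", "benchmark_error_counts.csv",
                              package = "stepdir"))
}
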