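# One-vs-rest classifier bank: one binary classifier per stepping motion,
# all sharing a backend and feature schema, plus arbitration of the five
# binary outputs into a single motion event.

#' The five stepping motions
#' @export
MOTION_LABELS <- c("jump", "left", "right", "forward", "backward")

CLASSIFY_BACKENDS <- c("svm", "knn", "decision_tree")

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- single binary classifier -------------------------------------------

train_motion_classifier <- function(x, ybin, backend, hyper) {
  stopifnot(is.matrix(x), nlevels(ybin) == 2)
  if (length(unique(ybin)) < 2)
    stop("degenerate training set: only one class present")
  n <- length(ybin)
  tab <- table(ybin)
  # inverse-frequency weights: each binary problem is roughly 1:3 imbalanced
  wts <- as.numeric(n / (2 * tab[ybin]))
  fit <- switch(backend,
    svm = e1071::svm(x, ybin, kernel = "radial", scale = TRUE,
                     class.weights = n / (2 * tab)),
    decision_tree = {
      df <- data.frame(x, .y = ybin, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class", weights = wts,
                   control = rpart::rpart.control(
                     maxdepth = hyper$maxdepth %||% 10,
                     cp = hyper$cp %||% 0.001, xval = 0))
    },
    knn = {
      k <- hyper$k %||% 5
      if (k > n) stop("knn: k larger than the training set")
      mu <- colMeans(x)
      sd_ <- apply(x, 2, stats::sd)
      sd_[sd_ == 0] <- 1
      list(train = scale(x, center = mu, scale = sd_),
           cl = ybin, k = k, center = mu, scale = sd_)
    })
  list(backend = backend, fit = fit, hyper = hyper)
}

# score > 0 <=> classifier fires for its motion
score_motion_classifier <- function(clf, x) {
  switch(clf$backend,
    svm = {
      dv <- attr(stats::predict(clf$fit, x, decision.values = TRUE),
                 "decision.values")
      # orient so positive decision value means the "pos" class
      if (grepl("^pos/", colnames(dv)[1])) as.numeric(dv) else -as.numeric(dv)
    },
    decision_tree = {
      pr <- stats::predict(clf$fit, data.frame(x, check.names = FALSE),
                           type = "prob")
      as.numeric(pr[, "pos"]) - 0.5
    },
    knn = {
      xs <- scale(x, center = clf$fit$center, scale = clf$fit$scale)
      pred <- class::knn(clf$fit$train, xs, clf$fit$cl, k = clf$fit$k,
                         prob = TRUE, use.all = TRUE)
      frac <- attr(pred, "prob")
      pos_frac <- ifelse(pred == "pos", frac, 1 - frac)
      pos_frac - 0.5
    })
}

# ---- bank ----------------------------------------------------------------

#' Train the one-vs-rest classifier bank
#'
#' Fits, for each of the five motions, a binary (motion vs rest) classifier
#' on the full training set. All five share one backend and one feature
#' schema. Inverse-frequency class weights compensate the inherent ~1:3
#' imbalance of each binary problem. Deterministic given `seed`.
#'
#' @param x Feature matrix (rows = windows, columns per [feature_schema()]).
#' @param labels Character/factor vector of true motions (subset of
#'   [MOTION_LABELS]).
#' @param backend `"svm"` (RBF kernel, internally unit-scaled features),
#'   `"knn"` (k nearest neighbours on standardised features, default k = 5)
#'   or `"decision_tree"` (Gini CART, depth cap 10).
#' @param hyper Optional list of backend hyperparameters (`k`, `maxdepth`,
#'   `cp`).
#' @param seed Integer RNG seed threaded through training.
#' @return Object of class `classifier_bank`.
#' @export
train_bank <- function(x, labels, backend = c("svm", "knn", "decision_tree"),
                       hyper = list(), seed = 1) {
  backend <- match.arg(backend)
  labels <- as.character(labels)
  if (!all(labels %in% MOTION_LABELS))
    stop("train_bank: labels must be among ", paste(MOTION_LABELS, collapse = ", "))
  if (length(unique(labels)) < 2)
    stop("degenerate training set: need at least two motion classes")
  x <- as.matrix(x)
  set.seed(seed)
  clfs <- lapply(MOTION_LABELS, function(m) {
    ybin <- factor(ifelse(labels == m, "pos", "neg"), levels = c("pos", "neg"))
    train_motion_classifier(x, ybin, backend, hyper)
  })
  names(clfs) <- MOTION_LABELS
  structure(list(backend = backend, classifiers = clfs,
                 schema = feature_schema(), seed = seed,
                 feature_names = colnames(x)),
            class = "classifier_bank")
}

check_schema <- function(bank, x) {
  if (!is.null(bank$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), bank$feature_names))
    stop("classifier_bank: feature schema mismatch")
  if (ncol(x) != length(bank$feature_names %||% colnames(x)))
    stop("classifier_bank: feature dimension mismatch")
}

#' Arbitrate per-motion scores into a single motion label
#'
#' A classifier "fires" when its score is positive. No classifier fires ->
#' `"none"`; exactly one -> that motion regardless of magnitude; several ->
#' the highest score, ties broken by the fixed motion order jump, left,
#' right, forward, backward. A pure function of the score matrix.
#'
#' @param scores Numeric matrix (rows = windows) with one column per
#'   motion, in [MOTION_LABELS] order.
#' @return Data frame with `label` (factor including `"none"`) and `score`
#'   (the winning score, `NA` when none fired).
#' @export
arbitrate <- function(scores) {
  scores <- matrix(scores, ncol = length(MOTION_LABELS),
                   dimnames = list(NULL, MOTION_LABELS))
  lab <- character(nrow(scores)); win <- rep(NA_real_, nrow(scores))
  for (i in seq_len(nrow(scores))) {
    fired <- which(scores[i, ] > 0)
    if (length(fired) == 0) {
      lab[i] <- "none"
    } else {
      # which.max returns the first maximum: the fixed motion order breaks ties
      j <- fired[which.max(scores[i, fired])]
      lab[i] <- MOTION_LABELS[j]
      win[i] <- scores[i, j]
    }
  }
  data.frame(label = factor(lab, levels = c(MOTION_LABELS, "none")),
             score = win)
}

#' Per-motion scores and arbitrated labels for a feature matrix
#'
#' Runs all five binary classifiers and applies [arbitrate()].
#'
#' @param bank A trained `classifier_bank`.
#' @param x Feature matrix with the bank's schema.
#' @return Data frame with `label`, `score`, and one score column per
#'   motion.
#' @export
predict_bank <- function(bank, x) {
  x <- if (is.null(dim(x))) matrix(x, 1, dimnames = list(NULL, names(x))) else as.matrix(x)
  check_schema(bank, x)
  scores <- vapply(MOTION_LABELS,
                   function(m) score_motion_classifier(bank$classifiers[[m]], x),
                   numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(NULL, MOTION_LABELS))
  cbind(arbitrate(scores), as.data.frame(scores))
}

#' Arbitrate a single feature vector into a motion event
#'
#' @param bank A trained `classifier_bank`.
#' @param fv Named feature vector (one window).
#' @return List with `label` (character) and `score`.
#' @export
predict_event <- function(bank, fv) {
  res <- predict_bank(bank, fv)
  list(label = as.character(res$label[1]), score = res$score[1])
}
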