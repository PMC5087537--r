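# five well-separated clusters in the 30-dimensional schema space; every
# dimension is informative so feature standardisation preserves separation
separable_features <- function(n_per = 12, seed = 41) {
  set.seed(seed)
  pattern <- sapply(1:30, function(j) 10 * (((j - 1) %% 5) + 1 == 1:5))
  centers <- pattern[rep(seq_len(5), each = n_per), ]
  x <- centers + matrix(rnorm(5 * n_per * 30, 0, 0.3), 5 * n_per, 30)
  colnames(x) <- feature_schema()$names
  list(x = x, y = rep(MOTION_LABELS, each = n_per))
}

test_that("all backends separate linearly separable clusters with full training recall", {
  d <- separable_features()
  for (backend in c("svm", "knn", "decision_tree")) {
    bank <- train_bank(d$x, d$y, backend, seed = 2)
    pred <- predict_bank(bank, d$x)
    expect_identical(as.character(pred$label), d$y)
  }
})

test_that("kNN predictions are invariant to training-row order and exact at k = 1", {
  d <- separable_features()
  bank1 <- train_bank(d$x, d$y, "knn", seed = 3)
  set.seed(44)
  perm <- sample(nrow(d$x))
  bank2 <- train_bank(d$x[perm, ], d$y[perm], "knn", seed = 3)
  expect_identical(as.character(predict_bank(bank1, d$x)$label),
                   as.character(predict_bank(bank2, d$x)$label))

  bank_k1 <- train_bank(d$x, d$y, "knn", hyper = list(k = 1), seed = 3)
  expect_identical(as.character(predict_bank(bank_k1, d$x)$label), d$y)
})

test_that("the 3-vs-2 neighbour toy flips class between k = 3 and k = 5", {
  # squares at distance 1 and 2; triangles at 1.5, 2.5, 2.6 (2-D, one axis)
  x <- cbind(c(1, -2, -1.5, 2.5, -2.6), 0)
  y <- factor(c("pos", "pos", "neg", "neg", "neg"), levels = c("pos", "neg"))
  test_pt <- matrix(c(0, 0), 1)
  k3 <- stepdir:::train_motion_classifier(x, y, "knn", list(k = 3))
  k5 <- stepdir:::train_motion_classifier(x, y, "knn", list(k = 5))
  expect_gt(stepdir:::score_motion_classifier(k3, test_pt), 0)  # 2 of 3 squares
  expect_lt(stepdir:::score_motion_classifier(k5, test_pt), 0)  # 3 of 5 triangles
  expect_error(stepdir:::train_motion_classifier(x, y, "knn", list(k = 6)),
               "larger")
})

test_that("the SVM boundary falls between two separated 1-D clusters", {
  x <- cbind(c(-1.6, -1.3, -1.1, -1.0, 1.0, 1.2, 1.4, 1.7),
             c(0.01, -0.01, 0.02, -0.02, 0.01, -0.01, 0.02, -0.02))
  y <- factor(rep(c("neg", "pos"), each = 4), levels = c("pos", "neg"))
  clf <- stepdir:::train_motion_classifier(x, y, "svm", list())
  sc <- stepdir:::score_motion_classifier(clf, x)
  expect_true(all(sc[y == "pos"] > 0) && all(sc[y == "neg"] < 0))
  grid <- cbind(seq(-1, 1, by = 0.01), 0)
  gs <- stepdir:::score_motion_classifier(clf, grid)
  crossing <- grid[min(which(gs > 0)), 1]
  expect_gt(crossing, -1); expect_lt(crossing, 1)
})

test_that("arbitration follows the none / single / max-score / fixed-order rules", {
  s <- function(...) matrix(c(...), 1)
  expect_identical(as.character(arbitrate(s(-1, -2, -0.1, -3, -0.5))$label), "none")
  expect_true(is.na(arbitrate(s(-1, -2, -0.1, -3, -0.5))$score))
  # exactly one fires: chosen regardless of magnitude
  expect_identical(as.character(arbitrate(s(-9, 0.01, -9, -9, -9))$label), "left")
  # several fire: larger margin wins
  expect_identical(as.character(arbitrate(s(0.2, 0.9, -1, 0.5, -1))$label), "left")
  # exact tie: fixed motion order jump > backward
  expect_identical(as.character(arbitrate(s(0.4, -1, -1, -1, 0.4))$label), "jump")
})

test_that("bank prediction is a deterministic pure function", {
  d <- separable_features()
  bank <- train_bank(d$x, d$y, "svm", seed = 5)
  p1 <- predict_bank(bank, d$x)
  for (r in 1:3) expect_identical(predict_bank(bank, d$x), p1)
  ev <- predict_event(bank, d$x[1, ])
  expect_identical(ev$label, as.character(p1$label[1]))
})

test_that("degenerate training sets and schema mismatches are rejected", {
  d <- separable_features()
  expect_error(train_bank(d$x[1:5, ], rep("jump", 5), "svm"), "degenerate")
  expect_error(train_bank(d$x, rep(c("up", "down"), 30), "svm"), "labels")
  bank <- train_bank(d$x, d$y, "svm", seed = 1)
  bad <- d$x[, c(2:30, 1)]
  expect_error(predict_bank(bank, bad), "schema")
  expect_error(predict_bank(bank, d$x[, 1:10]), "dimension|schema")
})

test_that("a held-out split of pipeline features classifies accurately at small scale", {
  corp <- small_corpus()
  ev <- evaluate_bank(corp$x, corp$y, backend = "svm", scheme = "holdout",
                      seed = 6)
  expect_gt(ev$macro_accuracy, 0.85)
})
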