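g0 <- 9.80665

test_that("means and population variances match hand arithmetic and a two-pass oracle", {
  w <- const_window(c(2.5, -1, g0))
  mv <- mean_variance(w)
  expect_equal(unname(mv$accel_mean), c(2.5, -1, g0))
  expect_equal(unname(mv$accel_var), c(0, 0, 0))

  # {1,2,3}: population variance 2/3, not the sample 1
  expect_equal(stepdir:::pop_var(c(1, 2, 3)), 2 / 3)

  set.seed(31)
  am <- matrix(rnorm(93), 31, 3); gm <- matrix(rnorm(93), 31, 3)
  mv3 <- mean_variance(make_test_window(am, gm))
  two_pass <- function(x) sum((x - sum(x) / length(x))^2) / length(x)
  expect_equal(unname(mv3$accel_var), apply(am, 2, two_pass), tolerance = 1e-12)
  expect_equal(unname(mv3$gyro_var), apply(gm, 2, two_pass), tolerance = 1e-12)
  expect_equal(unname(mv3$gyro_mean), colMeans(gm), tolerance = 1e-12)
})

test_that("SMA is the rectangular sum of |a| dt and is sign-invariant", {
  expect_equal(unname(sma(const_window(c(0, 0, 0)))), c(0, 0, 0))
  expect_equal(unname(sma(const_window(c(1, 1, 1)))), rep(31 / 200, 3))
  set.seed(32)
  a <- matrix(rnorm(93), 31, 3)
  expect_equal(sma(make_test_window(a)), sma(make_test_window(-a)),
               tolerance = 1e-12)
})

test_that("position change integrates gravity-free acceleration from rest", {
  expect_equal(position_change(const_window(c(0, 0, g0))), c(0, 0, 0))
  # constant 1 m/s^2 net up over the 0.15 s window: dz = a t^2 / 2
  p <- position_change(const_window(c(0, 0, g0 + 1)))
  expect_equal(p[3], 0.5 * 0.15^2, tolerance = 1e-9)
  expect_equal(p[1:2], c(0, 0))
})

test_that("a simulated left-step window displaces dominantly along the right axis", {
  cw <- clean_motion_windows(4)
  lefts <- which(cw$labels == "left")
  for (i in lefts) {
    p <- position_change(cw$windows[[i]])
    expect_gt(abs(p[1]), abs(p[2]))
    expect_gt(abs(p[1]), abs(p[3]))
    expect_lt(p[1], 0)   # left is -x in Right-Forward-Up
  }
})

test_that("ratio features normalise by the triple norm and handle zero norm", {
  expect_equal(ratio_feature(c(0, 0, 2)), c(0, 0, 1))
  r <- ratio_feature(c(0.2, 0.2, 0.5))
  expect_equal(r[3], 0.5 / sqrt(0.33), tolerance = 1e-4)
  expect_gt(r[3], 0.5)   # vertical share dominates for a heavy jump
  r2 <- ratio_feature(c(0.05, 0.05, 0.2))
  expect_equal(r2[3], 0.2 / sqrt(0.045), tolerance = 1e-4)
  expect_gt(r2[3], 0.5)  # ... and equally for a slight jump
  expect_equal(ratio_feature(c(0, 0, 0)), c(0, 0, 0))

  set.seed(33)
  for (i in 1:100) {
    v <- rnorm(3)
    expect_equal(sum(ratio_feature(v)^2), 1, tolerance = 1e-9)
  }
})

test_that("the feature vector is deterministic with the documented schema", {
  set.seed(34)
  w <- make_test_window(matrix(rnorm(93, 0, 3), 31, 3),
                        matrix(rnorm(93), 31, 3))
  f1 <- build_feature_vector(w); f2 <- build_feature_vector(w)
  expect_identical(f1, f2)
  expect_identical(names(f1), feature_schema()$names)
  expect_length(f1, 30)
  expect_identical(feature_schema()$version, 1L)
})

test_that("ratio features are strength-invariant while means and SMA scale", {
  set.seed(35)
  motion <- matrix(rnorm(93, 0, 4), 31, 3)
  grav <- matrix(rep(c(0, 0, g0), each = 31), 31, 3)
  w1 <- make_test_window(grav + motion)
  w2 <- make_test_window(grav + 2 * motion)       # doubled motion strength
  w2_all <- make_test_window(2 * (grav + motion)) # doubled raw signal
  f1 <- build_feature_vector(w1); f2 <- build_feature_vector(w2)
  f2a <- build_feature_vector(w2_all)

  # raw x2: accel means/SMA double, accel-derived ratios unchanged
  expect_equal(f2a[paste0("accel_mean_", c("x", "y", "z"))],
               2 * f1[paste0("accel_mean_", c("x", "y", "z"))], tolerance = 1e-12)
  expect_equal(f2a[paste0("accel_sma_", c("x", "y", "z"))],
               2 * f1[paste0("accel_sma_", c("x", "y", "z"))], tolerance = 1e-12)
  for (fam in c("ratio_mean_", "ratio_var_", "ratio_sma_"))
    expect_equal(f2a[paste0(fam, c("x", "y", "z"))],
                 f1[paste0(fam, c("x", "y", "z"))], tolerance = 1e-9)

  # doubled motion over fixed gravity: position doubles, its ratios do not
  expect_equal(f2[paste0("pos_", c("x", "y", "z"))],
               2 * f1[paste0("pos_", c("x", "y", "z"))], tolerance = 1e-9)
  expect_equal(f2[paste0("ratio_pos_", c("x", "y", "z"))],
               f1[paste0("ratio_pos_", c("x", "y", "z"))], tolerance = 1e-9)
})

test_that("jump windows carry a dominant vertical position-ratio signature", {
  cw <- clean_motion_windows(20)   # 100 windows per motion
  rz <- abs(cw$features[, "ratio_pos_z"])
  m_jump <- mean(rz[cw$labels == "jump"])
  for (m in setdiff(MOTION_LABELS, "jump"))
    expect_gt(m_jump, mean(rz[cw$labels == m]))
  expect_gt(m_jump, 0.5)
})
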