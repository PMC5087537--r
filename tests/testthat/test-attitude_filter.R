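g0 <- 9.80665

test_that("Euler/DCM/quaternion conversions are mutually consistent", {
  set.seed(5)
  for (i in 1:50) {
    e <- runif(3, -1.2, 1.2)
    C <- euler_to_dcm(e[1], e[2], e[3])
    expect_equal(max(abs(C %*% t(C) - diag(3))), 0, tolerance = 1e-12)
    expect_equal(det(C), 1, tolerance = 1e-12)
    expect_equal(unname(dcm_to_euler(C)), e, tolerance = 1e-9)
    expect_equal(stepdir:::quat_to_dcm(stepdir:::dcm_to_quat(C)), C, tolerance = 1e-9)
  }
})

test_that("prediction with zero gyro and zero bias leaves attitude fixed and inflates P by Q", {
  cfg <- filter_config()
  st <- attitude_state(euler_to_dcm(0.2, -0.1, 0.3))
  out <- attitude_predict(st, c(0, 0, 0), 0.005, cfg)
  expect_equal(attitude_dcm(out), attitude_dcm(st), tolerance = 1e-12)
  dP <- diag(out$P - st$P)
  expect_true(all(dP >= c(rep(cfg$q_gyro, 3), rep(0, 3)) * 0.005 - 1e-12))
  expect_error(attitude_predict(st, c(0, 0, 0), 0, cfg), "dt")
  expect_error(attitude_predict(st, c(NA, 0, 0), 0.005, cfg), "finite")
})

test_that("constant z-rate integrates to a pure yaw of 90 degrees", {
  cfg <- filter_config()
  st <- attitude_state()
  for (i in 1:200) st <- attitude_predict(st, c(0, 0, pi / 2), 1 / 200, cfg)
  e <- dcm_to_euler(attitude_dcm(st))
  expect_equal(e[["yaw"]], pi / 2, tolerance = 1e-9)
  expect_equal(e[["pitch"]], 0, tolerance = 1e-9)
  expect_equal(e[["roll"]], 0, tolerance = 1e-9)
})

test_that("dynamic index equals |norm - g| (brute-force oracle)", {
  expect_equal(dynamic_index(c(0, 0, g0), g0), 0)
  expect_equal(dynamic_index(c(0, 0, 3 * g0), g0), 2 * g0)
  set.seed(8)
  v <- matrix(rnorm(3000, 0, 8), 1000)
  oracle <- apply(v, 1, function(r) abs(sqrt(sum(r^2)) - g0))
  expect_equal(dynamic_index(v, g0), oracle, tolerance = 1e-12)
})

test_that("mode selection matches a literal three-branch reference over a sweep", {
  cfg <- filter_config()
  expect_identical(select_mode(0, cfg)$mode, "stationary")
  expect_equal(select_mode(0, cfg)$R, cfg$R0)
  hd <- select_mode(2 * g0, cfg)
  expect_identical(hd$mode, "high_dynamic")
  expect_null(hd$R)

  reference <- function(idx) {
    if (idx < cfg$thres1) list("stationary", cfg$R0)
    else if (idx < cfg$thres2) list("low_acceleration",
                                    cfg$R0 + diag(cfg$k_scale * idx^2, 3))
    else list("high_dynamic", NULL)
  }
  set.seed(9)
  sweep <- c(runif(9000, 0, 3 * g0),
             runif(1000, 0, 3 * cfg$thres1))  # dense near the lower branch
  for (idx in sweep[1:200]) {  # matrix comparison on a subsample
    got <- select_mode(idx, cfg); ref <- reference(idx)
    expect_identical(got$mode, ref[[1]])
    expect_equal(got$R, ref[[2]])
  }
  modes <- vapply(sweep, function(i) select_mode(i, cfg)$mode, character(1))
  ref_modes <- vapply(sweep, function(i) reference(i)[[1]], character(1))
  expect_identical(modes, ref_modes)
})

test_that("gravity residual vanishes at perfect attitude and follows the small-angle law", {
  st <- attitude_state(euler_to_dcm(0.3, -0.2, 0))
  static_meas <- as.numeric(t(attitude_dcm(st)) %*% c(0, 0, g0))
  expect_equal(acc_residual(static_meas, st, g0), c(0, 0, 0), tolerance = 1e-12)

  # 1 degree of roll error: residual magnitude ~ g * sin(1 deg)
  err <- 1 * pi / 180
  st_err <- attitude_state(euler_to_dcm(0, err, 0))
  res <- acc_residual(c(0, 0, g0), st_err, g0)
  # exact magnitude is 2 g sin(err/2); g sin(err) to first order
  expect_equal(sqrt(sum(res^2)), g0 * sin(err), tolerance = 1e-4)
})

test_that("residual linearisation matches C %*% [a_n x] %*% psi to first order", {
  set.seed(11)
  for (i in 1:30) {
    C <- euler_to_dcm(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
    psi <- runif(3, -1, 1)
    psi <- psi / sqrt(sum(psi^2)) * (1 * pi / 180)   # 1 degree error
    # truth attitude differs from the computed one by psi
    C_true <- (diag(3) + stepdir:::skew(psi)) %*% C
    meas <- as.numeric(t(C_true) %*% c(0, 0, g0))
    res <- acc_residual(meas, attitude_state(C), g0)
    lin <- as.numeric(t(C) %*% stepdir:::skew(c(0, 0, g0)) %*% psi)
    expect_lt(sqrt(sum((res - lin)^2)) / sqrt(sum(lin^2)), 0.02)
  }
})

test_that("measurement matrix has the +/- g pattern, a zero bias block, and matches a finite-difference Jacobian", {
  H0 <- measurement_matrix(attitude_state(diag(3)), g0)
  expect_equal(H0[, 1:3],
               matrix(c(0, -g0, 0, g0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(H0[, 4:6], matrix(0, 3, 3))

  set.seed(12)
  for (i in 1:10) {
    C <- euler_to_dcm(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
    st <- attitude_state(C)
    expect_equal(measurement_matrix(st, g0)[, 4:6], matrix(0, 3, 3))
    meas <- rnorm(3, 0, 3)
    # perturbing the computed attitude by feedback psi0 changes the
    # residual by -H_att %*% psi0
    eps <- 1e-6
    J <- sapply(1:3, function(j) {
      d <- numeric(3); d[j] <- eps
      Cp <- (diag(3) + stepdir:::skew(d)) %*% C
      (acc_residual(meas, attitude_state(Cp), g0) -
         acc_residual(meas, st, g0)) / eps
    })
    expect_equal(J, -measurement_matrix(st, g0)[, 1:3], tolerance = 1e-4)
  }
})

test_that("zero-residual updates leave the attitude fixed while shrinking P", {
  st <- attitude_state(euler_to_dcm(0.1, 0.2, 0))
  H <- measurement_matrix(st, g0)
  out <- attitude_update(st, c(0, 0, 0), H, diag(0.0025, 3))
  expect_equal(attitude_dcm(out), attitude_dcm(st), tolerance = 1e-12)
  expect_equal(out$bias, st$bias)
  expect_lt(sum(diag(out$P)), sum(diag(st$P)))
})

test_that("P stays symmetric positive semi-definite over long random update sequences", {
  set.seed(13)
  cfg <- filter_config()
  st <- attitude_state()
  for (i in 1:2000) {
    st <- attitude_predict(st, rnorm(3, 0, 0.5), 0.005, cfg)
    if (i %% 2 == 0) {
      H <- measurement_matrix(st, g0)
      st <- attitude_update(st, rnorm(3, 0, 0.1), H, diag(0.0025, 3))
    }
    C <- attitude_dcm(st)
    expect_lt(max(abs(C %*% t(C) - diag(3))), 1e-9)
  }
  expect_equal(st$P, t(st$P), tolerance = 1e-12)
  expect_true(all(eigen(st$P, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
})

test_that("a 10-degree initial roll error converges below 0.5 degrees on static data", {
  cfg <- filter_config()
  set.seed(14)
  st <- attitude_state(euler_to_dcm(0, 10 * pi / 180, 0),
                       P = diag(c(rep(cfg$init_att_sd^2, 3),
                                  rep(cfg$init_bias_sd^2, 3))))
  for (i in 1:1000) {   # 5 s at 200 Hz, truth attitude = identity
    meas <- c(0, 0, g0) + rnorm(3, 0, 0.05)
    st <- attitude_predict(st, rnorm(3, 0, 0.01), 1 / 200, cfg)
    sel <- select_mode(dynamic_index(meas, g0), cfg)
    if (sel$mode != "high_dynamic")
      st <- attitude_update(st, acc_residual(meas, st, g0),
                            measurement_matrix(st, g0), sel$R)
  }
  e <- dcm_to_euler(attitude_dcm(st))
  expect_lt(abs(e[["roll"]]) * 180 / pi, 0.5)
  expect_lt(abs(e[["pitch"]]) * 180 / pi, 0.5)
})

test_that("with updates disabled the filter reduces to pure gyro integration", {
  set.seed(15)
  base <- motion_profile("forward", gyro_bias = c(0, 0, 0),
                         misalignment_deg = c(8, -4))
  ses <- simulate_session("forward", base = base, seed = 16, noise = FALSE)
  cfg_off <- filter_config(update_enabled = FALSE)
  tr <- run_attitude_filter(ses$stream, cfg_off)
  # reference: straight quaternion integration from the same leveled start
  gyro <- as.matrix(as.data.frame(ses$stream)[, c("gx", "gy", "gz")])
  n_init <- sum(ses$stream$t - ses$stream$t[1] <= cfg_off$init_window_s)
  st <- init_attitude(as.matrix(as.data.frame(ses$stream)[seq_len(n_init),
                                                          c("ax", "ay", "az")]),
                      cfg_off)
  q <- st$q
  for (i in 2:nrow(ses$stream))
    q <- stepdir:::quat_normalize(
      stepdir:::quat_mul(q, stepdir:::quat_from_rotvec(gyro[i, ] / 200)))
  expect_equal(stepdir:::quat_to_dcm(q),
               stepdir:::quat_to_dcm(attr(tr, "quat")[nrow(ses$stream), ]),
               tolerance = 1e-9)
})

test_that("user-frame projection preserves norms and levels a tilted sensor", {
  # identity attitude: projection is the identity
  s <- imu_stream((0:9) / 200, matrix(rnorm(30), 10), matrix(rnorm(30), 10))
  cfg <- filter_config()
  st_track <- run_attitude_filter(
    imu_stream((0:9) / 200, matrix(0, 10, 3),
               matrix(rep(c(0, 0, g0), each = 10), 10, 3)), cfg)
  out <- to_user_frame(s, st_track)
  expect_equal(imu_accel(out), imu_accel(s), tolerance = 1e-9)

  # sensor pitched 30 degrees, static: projected accel is (0, 0, g)
  prof <- motion_profile("forward", misalignment_deg = c(30, 0),
                         gyro_bias = c(0, 0, 0))
  st2 <- simulate_static(2, prof, noise = FALSE)
  tr2 <- run_attitude_filter(st2, cfg)
  u2 <- to_user_frame(st2, tr2)
  expect_equal(unname(colMeans(imu_accel(u2)[200:400, ])), c(0, 0, g0),
               tolerance = 1e-6)
  # rotations preserve the norm sample-by-sample
  expect_equal(sqrt(rowSums(imu_accel(u2)^2)),
               sqrt(rowSums(imu_accel(st2)^2)), tolerance = 1e-9)
  expect_identical(imu_frame(u2), "user")
})

test_that("quaternion DCMs remain orthonormal through a full filtered session", {
  ses <- small_session()
  tr <- run_attitude_filter(compensate(ses$stream, calibration_params()))
  q <- attr(tr, "quat")
  for (i in seq(1, nrow(q), by = 97)) {
    C <- stepdir:::quat_to_dcm(q[i, ])
    expect_lt(max(abs(C %*% t(C) - diag(3))), 1e-9)
    expect_equal(det(C), 1, tolerance = 1e-9)
  }
})
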