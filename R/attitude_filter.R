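# Error-state Kalman attitude filter.
#
# The full attitude (quaternion, body -> navigation) is integrated from the
# bias-corrected gyroscope; a 6-state error filter (attitude error psi,
# gyro-bias error db) observes the accelerometer's gravity residual and
# feeds corrections back. Error dynamics (Earth rate and transport rate are
# negligible against MEMS bias at desk scale and are set to zero):
#
#   psi_dot = -C_b_n %*% db
#   db_dot  = -(1/tau_b) * db + w        (first-order Gauss-Markov bias)
#
# Measurement: the body-frame difference between the measured specific
# force and the projection of the at-rest specific force a_n = (0, 0, +g)
# through the computed attitude,
#
#   z = f_meas^b - t(C_b_n) %*% a_n  ~=  t(C_b_n) %*% skew(a_n) %*% psi.
#
# The measurement covariance R is tuned adaptively from the dynamic index
# |‖f‖ - g|: stationary (R = R0), low acceleration (R = R0 + k * idx^2 * I),
# high dynamic (no update; prediction only).

#' Attitude filter configuration
#'
#' @param tau_b Gyro-bias Gauss-Markov correlation time (s).
#' @param q_gyro Attitude process-noise spectral density (rad^2/s); driven
#'   by gyro angle random walk.
#' @param q_bias Bias process-noise spectral density ((rad/s)^2/s); for a
#'   Gauss-Markov bias with steady-state sd `sigma_b`, `2 * sigma_b^2 / tau_b`.
#' @param g Local gravity (m/s^2).
#' @param accel_noise_std Per-axis accelerometer per-sample noise sd
#'   (m/s^2); sets `R0 = diag(sd^2)` and the default stationary threshold.
#' @param thres1 Stationary-mode threshold (m/s^2). Default is the sum-of-
#'   variances rule `3 * sum(sd^2)` (see `thres1_mode`).
#' @param thres1_mode `"variance"` uses `3 * sum(sd^2)` verbatim;
#'   `"std"` uses the dimensionally consistent `3 * sqrt(sum(sd^2))`.
#' @param thres2 High-dynamic threshold (m/s^2); default `2 * g`.
#' @param k_scale Dimensionless inflation gain for the low-acceleration
#'   measurement covariance `R = R0 + k_scale * idx^2 * I`.
#' @param init_window_s Length of the assumed-static leveling window used to
#'   initialise pitch/roll from the accelerometer.
#' @param init_att_sd,init_bias_sd Initial 1-sigma attitude (rad) and bias
#'   (rad/s) uncertainty.
#' @param update_enabled Set `FALSE` to disable all measurement updates
#'   (pure gyro integration).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(tau_b = 100,
                          q_gyro = 1e-6,
                          q_bias = 5e-5,
                          g = 9.80665,
                          accel_noise_std = c(0.05, 0.05, 0.05),
                          thres1 = NULL,
                          thres1_mode = c("variance", "std"),
                          thres2 = NULL,
                          k_scale = 100,
                          init_window_s = 0.5,
                          init_att_sd = 5 * pi / 180,
                          init_bias_sd = 0.05,
                          update_enabled = TRUE) {
  thres1_mode <- match.arg(thres1_mode)
  if (is.null(thres2)) thres2 <- 2 * g
  if (is.null(thres1)) {
    ss <- sum(accel_noise_std^2)
    thres1 <- if (thres1_mode == "variance") 3 * ss else 3 * sqrt(ss)
  }
  stopifnot(tau_b > 0, g > 0, thres1 > 0, thres1 < thres2, k_scale >= 0)
  structure(list(tau_b = tau_b, q_gyro = q_gyro, q_bias = q_bias, g = g,
                 accel_noise_std = as.numeric(accel_noise_std),
                 R0 = diag(as.numeric(accel_noise_std)^2, 3),
                 thres1 = thres1, thres1_mode = thres1_mode, thres2 = thres2,
                 k_scale = k_scale, init_window_s = init_window_s,
                 init_att_sd = init_att_sd, init_bias_sd = init_bias_sd,
                 update_enabled = update_enabled),
            class = "filter_config")
}

#' Construct an attitude state
#'
#' @param C_b_n 3x3 body-to-navigation rotation.
#' @param bias Current gyro-bias estimate (rad/s).
#' @param P 6x6 error covariance (attitude error, bias error).
#' @param t Time stamp (s).
#' @return Object of class `attitude_state` (quaternion held internally).
#' @export
attitude_state <- function(C_b_n = diag(3), bias = c(0, 0, 0),
                           P = diag(c(rep((5 * pi / 180)^2, 3), rep(0.05^2, 3))),
                           t = 0) {
  structure(list(q = dcm_to_quat(C_b_n), bias = as.numeric(bias),
                 P = P, t = t), class = "attitude_state")
}

#' Body-to-navigation DCM of an attitude state
#' @param state An `attitude_state`.
#' @export
attitude_dcm <- function(state) quat_to_dcm(state$q)

#' System dynamic index
#'
#' The absolute departure of the measured specific-force norm from local
#' gravity, `| ||accel|| - g |`; zero when stationary.
#'
#' @param accel Length-3 specific-force vector (m/s^2) or n x 3 matrix.
#' @param g Local gravity (m/s^2).
#' @return Index in m/s^2 (vectorised over rows for a matrix).
#' @export
dynamic_index <- function(accel, g = 9.80665) {
  if (is.matrix(accel)) abs(sqrt(rowSums(accel^2)) - g)
  else abs(sqrt(sum(accel^2)) - g)
}

#' Select the filter's dynamic mode and measurement covariance
#'
#' Three-branch rule on the dynamic index: below `thres1` the carrier is
#' stationary and `R = R0`; between the thresholds the residual is usable
#' but down-weighted, `R = R0 + k_scale * index^2 * I`; at or above `thres2`
#' the accelerometer is dominated by motion and the measurement update is
#' skipped entirely.
#'
#' @param index Dynamic index (m/s^2), from [dynamic_index()].
#' @param cfg A [filter_config()].
#' @return List with `mode` (one of `"stationary"`, `"low_acceleration"`,
#'   `"high_dynamic"`) and `R` (3x3 matrix, or `NULL` in high-dynamic mode).
#' @export
select_mode <- function(index, cfg) {
  if (index < cfg$thres1) {
    list(mode = "stationary", R = cfg$R0)
  } else if (index < cfg$thres2) {
    list(mode = "low_acceleration", R = cfg$R0 + diag(cfg$k_scale * index^2, 3))
  } else {
    list(mode = "high_dynamic", R = NULL)
  }
}

#' Kalman prediction step
#'
#' Integrates the quaternion with the bias-corrected angular rate and
#' propagates the error covariance with the linearised transition
#' `Phi = [[I, -C*dt], [0, (1 - dt/tau_b)*I]]`.
#'
#' @param state An `attitude_state`.
#' @param gyro Measured angular rate (rad/s, body frame, length 3).
#' @param dt Time step (s), `> 0`.
#' @param cfg A [filter_config()].
#' @return The predicted `attitude_state`.
#' @export
attitude_predict <- function(state, gyro, dt, cfg) {
  if (!is.finite(dt) || dt <= 0) stop("attitude_predict: dt must be > 0")
  if (any(!is.finite(gyro))) stop("attitude_predict: non-finite gyro")
  w <- gyro - state$bias
  q <- quat_normalize(quat_mul(state$q, quat_from_rotvec(w * dt)))
  C <- quat_to_dcm(q)
  Phi <- diag(6)
  Phi[1:3, 4:6] <- -C * dt
  Phi[4:6, 4:6] <- diag(3) * (1 - dt / cfg$tau_b)
  Q <- diag(c(rep(cfg$q_gyro * dt, 3), rep(cfg$q_bias * dt, 3)))
  P <- Phi %*% state$P %*% t(Phi) + Q
  structure(list(q = q, bias = state$bias, P = (P + t(P)) / 2,
                 t = state$t + dt), class = "attitude_state")
}

#' Accelerometer gravity residual
#'
#' Body-frame difference between the measured specific force and the
#' projection of the at-rest specific force `(0, 0, g)` through the
#' computed attitude.
#'
#' @param accel_body Measured specific force (body frame, m/s^2).
#' @param state An `attitude_state`.
#' @param g Local gravity (m/s^2).
#' @return Length-3 residual (m/s^2).
#' @export
acc_residual <- function(accel_body, state, g = 9.80665) {
  C <- attitude_dcm(state)
  as.numeric(accel_body - t(C) %*% c(0, 0, g))
}

#' Measurement matrix of the gravity residual
#'
#' First-order sensitivity of [acc_residual()] to the attitude error:
#' `H = [ t(C_b_n) %*% skew(c(0, 0, g)) | 0_{3x3} ]`. The bias block is
#' identically zero — bias reaches the measurement only through the
#' propagated attitude error.
#'
#' @param state An `attitude_state`.
#' @param g Local gravity (m/s^2).
#' @return 3x6 matrix.
#' @export
measurement_matrix <- function(state, g = 9.80665) {
  C <- attitude_dcm(state)
  cbind(t(C) %*% skew(c(0, 0, g)), matrix(0, 3, 3))
}

#' Kalman measurement update with feedback
#'
#' Standard update of the 6-dimensional error state followed by immediate
#' feedback: the attitude error is folded into the quaternion (small-angle
#' correction, then renormalisation), the bias error into the bias
#' estimate, and the error state is reset to zero.
#'
#' @param state Predicted `attitude_state`.
#' @param residual Measurement residual from [acc_residual()].
#' @param H 3x6 measurement matrix.
#' @param R 3x3 measurement covariance.
#' @return The corrected `attitude_state`.
#' @export
attitude_update <- function(state, residual, H, R) {
  P <- state$P
  S <- H %*% P %*% t(H) + R
  S <- (S + t(S)) / 2
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) stop("attitude_update: innovation covariance not positive definite")
  K <- P %*% t(H) %*% chol2inv(ch)
  dx <- as.numeric(K %*% residual)
  IKH <- diag(6) - K %*% H
  P <- IKH %*% P %*% t(IKH) + K %*% R %*% t(K)   # Joseph form
  psi <- dx[1:3]
  q <- quat_normalize(quat_mul(quat_from_rotvec(psi), state$q))
  structure(list(q = q, bias = state$bias + dx[4:6],
                 P = (P + t(P)) / 2, t = state$t), class = "attitude_state")
}

#' Initial attitude from accelerometer leveling
#'
#' Pitch/roll from the mean specific force over an assumed-static window;
#' yaw fixed at zero by the user-frame definition.
#'
#' @param accel n x 3 matrix of static specific-force samples.
#' @param cfg A [filter_config()].
#' @param t Time stamp for the state.
#' @return An `attitude_state`.
#' @export
init_attitude <- function(accel, cfg, t = 0) {
  f <- colMeans(matrix(accel, ncol = 3))
  fn <- f / sqrt(sum(f^2))
  pitch <- asin(max(-1, min(1, fn[2])))
  roll <- atan2(-fn[1], fn[3])
  attitude_state(euler_to_dcm(pitch, roll, 0),
                 P = diag(c(rep(cfg$init_att_sd^2, 3),
                            rep(cfg$init_bias_sd^2, 3))),
                 t = t)
}

#' Run the attitude filter over a stream
#'
#' Initialises pitch/roll by accelerometer leveling over the first
#' `init_window_s` seconds (assumed static), then alternates prediction and
#' mode-gated measurement updates over every sample.
#'
#' @param stream Compensated `imu_stream` in the sensor frame.
#' @param cfg A [filter_config()].
#' @return An `attitude_track`: data frame `t, pitch, roll, yaw, mode`
#'   (angles rad) with attached per-sample quaternion and bias matrices.
#' @export
run_attitude_filter <- function(stream, cfg = filter_config()) {
  if (imu_frame(stream) != "sensor")
    stop("run_attitude_filter: expecting a sensor-frame stream")
  n <- nrow(stream)
  gyro <- imu_gyro(stream); accel <- imu_accel(stream)
  t <- stream$t
  n_init <- max(2, sum(t - t[1] <= cfg$init_window_s))
  state <- init_attitude(accel[seq_len(n_init), , drop = FALSE], cfg, t = t[1])

  quat <- matrix(0, n, 4); bias <- matrix(0, n, 3)
  euler <- matrix(0, n, 3); mode <- character(n)
  quat[1, ] <- state$q; bias[1, ] <- state$bias
  euler[1, ] <- dcm_to_euler(attitude_dcm(state)); mode[1] <- "stationary"

  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    state <- attitude_predict(state, gyro[i, ], dt, cfg)
    sel <- select_mode(dynamic_index(accel[i, ], cfg$g), cfg)
    if (cfg$update_enabled && sel$mode != "high_dynamic") {
      z <- acc_residual(accel[i, ], state, cfg$g)
      H <- measurement_matrix(state, cfg$g)
      state <- attitude_update(state, z, H, sel$R)
    }
    quat[i, ] <- state$q; bias[i, ] <- state$bias
    euler[i, ] <- dcm_to_euler(attitude_dcm(state)); mode[i] <- sel$mode
  }
  out <- data.frame(t = t, pitch = euler[, 1], roll = euler[, 2],
                    yaw = euler[, 3], mode = mode)
  structure(out, quat = quat, bias = bias, g = cfg$g,
            class = c("attitude_track", "data.frame"))
}

#' Project a sensor-frame stream into the user frame
#'
#' Rotates accelerometer and gyroscope measurements by the pitch/roll part
#' of the filtered attitude only — yaw is stripped, since the sensor's
#' forward axis is mounted along the foot's forward direction. The output
#' axes are Right (x), Forward (y), Up (z); at rest the projected specific
#' force is `(0, 0, +g)` regardless of mounting pitch/roll.
#'
#' @param stream Compensated sensor-frame `imu_stream`.
#' @param track An `attitude_track` aligned sample-for-sample with `stream`
#'   (same time stamps).
#' @return A user-frame `imu_stream`.
#' @export
to_user_frame <- function(stream, track) {
  if (imu_frame(stream) != "sensor")
    stop("to_user_frame: stream must be in the sensor frame")
  if (nrow(stream) != nrow(track))
    stop("to_user_frame: stream and attitude track lengths differ")
  if (max(abs(stream$t - track$t)) > 0.1)
    warning("to_user_frame: attitude track is stale (time gap > 0.1 s)")
  q <- attr(track, "quat")
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # vectorised quaternion -> DCM elements (body -> navigation)
  C11 <- 1 - 2 * (y^2 + z^2); C12 <- 2 * (x * y - w * z); C13 <- 2 * (x * z + w * y)
  C21 <- 2 * (x * y + w * z); C22 <- 1 - 2 * (x^2 + z^2); C23 <- 2 * (y * z - w * x)
  C31 <- 2 * (x * z - w * y); C32 <- 2 * (y * z + w * x); C33 <- 1 - 2 * (x^2 + y^2)
  yaw <- atan2(-C12, C22)
  cy <- cos(yaw); sy <- sin(yaw)
  rot <- function(vx, vy, vz) {
    nx <- C11 * vx + C12 * vy + C13 * vz
    ny <- C21 * vx + C22 * vy + C23 * vz
    nz <- C31 * vx + C32 * vy + C33 * vz
    # premultiply Rz(-yaw): strips the (unobservable) heading
    cbind(cy * nx + sy * ny, -sy * nx + cy * ny, nz)
  }
  a <- rot(stream$ax, stream$ay, stream$az)
  g <- rot(stream$gx, stream$gy, stream$gz)
  imu_replace(stream, gyro = g, accel = a, frame = "user")
}
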