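# Data model for six-axis inertial streams plus deterministic sensor-error
# compensation. The error model for both triads is
#
#   measured = true + bias + (S + N) %*% true + noise
#
# with S the (diagonal-dominant) scale-factor matrix and N the axis
# non-orthogonality matrix; compensation inverts the deterministic part
# exactly: true = solve(I + S + N, measured - bias). The stochastic term is
# deliberately not touched here — it is handled downstream by smoothing and
# by the attitude filter.

IMU_FRAMES <- c("sensor", "user", "navigation")

#' Construct an IMU stream
#'
#' An `imu_stream` is a data frame with columns `t, gx, gy, gz, ax, ay, az`
#' (seconds, rad/s, m/s^2 specific force) carrying a frame tag and a nominal
#' sampling rate.
#'
#' @param t Numeric vector of strictly increasing timestamps (s).
#' @param gyro n x 3 matrix of angular rates (rad/s).
#' @param accel n x 3 matrix of specific force (m/s^2).
#' @param frame One of `"sensor"`, `"user"`, `"navigation"`.
#' @param rate_hz Nominal sampling frequency; default 200.
#' @return An object of class `imu_stream`.
#' @export
imu_stream <- function(t, gyro, accel, frame = "sensor", rate_hz = 200) {
  frame <- match.arg(frame, IMU_FRAMES)
  gyro <- matrix(as.numeric(gyro), ncol = 3)
  accel <- matrix(as.numeric(accel), ncol = 3)
  stopifnot(length(t) == nrow(gyro), nrow(gyro) == nrow(accel))
  if (any(!is.finite(t)) || any(!is.finite(gyro)) || any(!is.finite(accel)))
    stop("imu_stream: non-finite values")
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("imu_stream: timestamps must be strictly increasing")
    nominal <- 1 / rate_hz
    if (abs(stats::median(dt) - nominal) > 0.1 * nominal)
      stop("imu_stream: median sampling interval departs from nominal rate by > 10%")
  }
  out <- data.frame(t = t,
                    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
                    ax = accel[, 1], ay = accel[, 2], az = accel[, 3])
  structure(out, frame = frame, rate_hz = rate_hz,
            class = c("imu_stream", "data.frame"))
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %d samples, frame = %s, nominal %g Hz, span %.3f s\n",
              nrow(x), imu_frame(x), attr(x, "rate_hz"),
              if (nrow(x) > 1) x$t[nrow(x)] - x$t[1] else 0))
  invisible(x)
}

#' Frame tag of an IMU stream
#' @param stream An `imu_stream`.
#' @return `"sensor"`, `"user"` or `"navigation"`.
#' @export
imu_frame <- function(stream) attr(stream, "frame")

imu_gyro <- function(stream) as.matrix(stream[, c("gx", "gy", "gz")])
imu_accel <- function(stream) as.matrix(stream[, c("ax", "ay", "az")])

# rebuild a stream with replaced kinematics, preserving metadata
imu_replace <- function(stream, gyro = NULL, accel = NULL, frame = NULL) {
  g <- if (is.null(gyro)) imu_gyro(stream) else gyro
  a <- if (is.null(accel)) imu_accel(stream) else accel
  imu_stream(stream$t, g, a,
             frame = if (is.null(frame)) imu_frame(stream) else frame,
             rate_hz = attr(stream, "rate_hz"))
}

#' Sensor calibration parameters
#'
#' Holds per-triad bias vectors, scale-factor and non-orthogonality matrices
#' and per-sample noise standard deviations. Defaults are an identity
#' calibration (no deterministic error, no noise).
#'
#' @param gyro_bias,accel_bias Length-3 bias vectors (rad/s, m/s^2).
#' @param gyro_scale,accel_scale 3x3 scale-factor error matrices.
#' @param gyro_nonorth,accel_nonorth 3x3 non-orthogonality matrices.
#' @param gyro_noise_std,accel_noise_std Length-3 per-sample noise standard
#'   deviations (rad/s, m/s^2); the accelerometer values also set the
#'   attitude filter's measurement covariance and stationary threshold.
#' @return Object of class `calibration_params`.
#' @export
calibration_params <- function(gyro_bias = c(0, 0, 0),
                               accel_bias = c(0, 0, 0),
                               gyro_scale = matrix(0, 3, 3),
                               accel_scale = matrix(0, 3, 3),
                               gyro_nonorth = matrix(0, 3, 3),
                               accel_nonorth = matrix(0, 3, 3),
                               gyro_noise_std = c(0, 0, 0),
                               accel_noise_std = c(0, 0, 0)) {
  cal <- list(gyro_bias = as.numeric(gyro_bias),
              accel_bias = as.numeric(accel_bias),
              gyro_scale = as.matrix(gyro_scale),
              accel_scale = as.matrix(accel_scale),
              gyro_nonorth = as.matrix(gyro_nonorth),
              accel_nonorth = as.matrix(accel_nonorth),
              gyro_noise_std = as.numeric(gyro_noise_std),
              accel_noise_std = as.numeric(accel_noise_std))
  stopifnot(length(cal$gyro_bias) == 3, length(cal$accel_bias) == 3,
            all(dim(cal$gyro_scale) == c(3, 3)),
            all(dim(cal$accel_scale) == c(3, 3)),
            all(dim(cal$gyro_nonorth) == c(3, 3)),
            all(dim(cal$accel_nonorth) == c(3, 3)))
  if (any(cal$gyro_noise_std < 0) || any(cal$accel_noise_std < 0))
    stop("calibration_params: noise standard deviations must be >= 0")
  for (m in list(diag(3) + cal$gyro_scale + cal$gyro_nonorth,
                 diag(3) + cal$accel_scale + cal$accel_nonorth)) {
    if (rcond(m) < 1e-12)
      stop("calibration_params: (I + S + N) is numerically singular")
  }
  structure(cal, class = "calibration_params")
}

#' Apply the forward sensor-error model
#'
#' Turns a true (error-free) sensor-frame stream into what the instrument
#' would measure: adds bias, scale-factor and non-orthogonality effects and,
#' optionally, Gaussian per-sample noise. This is the exact forward model
#' that [compensate()] inverts; the synthetic generator uses it to corrupt
#' ideal signals.
#'
#' @param stream `imu_stream` in the sensor frame holding true quantities.
#' @param cal A [calibration_params()] object.
#' @param noise If `TRUE`, add Gaussian noise with the calibration's
#'   per-sample standard deviations (uses the current RNG state).
#' @return The measured `imu_stream` (sensor frame).
#' @export
apply_sensor_errors <- function(stream, cal, noise = FALSE) {
  stopifnot(inherits(cal, "calibration_params"))
  if (imu_frame(stream) != "sensor")
    stop("apply_sensor_errors: stream must be in the sensor frame")
  n <- nrow(stream)
  Mg <- diag(3) + cal$gyro_scale + cal$gyro_nonorth
  Ma <- diag(3) + cal$accel_scale + cal$accel_nonorth
  g_meas <- imu_gyro(stream) %*% t(Mg) +
    matrix(cal$gyro_bias, n, 3, byrow = TRUE)
  a_meas <- imu_accel(stream) %*% t(Ma) +
    matrix(cal$accel_bias, n, 3, byrow = TRUE)
  if (noise) {
    g_meas <- g_meas + matrix(stats::rnorm(3 * n, sd = rep(cal$gyro_noise_std, each = n)), n, 3)
    a_meas <- a_meas + matrix(stats::rnorm(3 * n, sd = rep(cal$accel_noise_std, each = n)), n, 3)
  }
  imu_replace(stream, gyro = g_meas, accel = a_meas)
}

#' Compensate deterministic sensor errors
#'
#' Exact inversion of the deterministic part of the sensor-error model:
#' `true = solve(I + S + N, measured - bias)` per triad. Stochastic noise is
#' left in place.
#'
#' @param stream Measured `imu_stream`, sensor frame.
#' @param cal A [calibration_params()] object.
#' @return Compensated `imu_stream` (still sensor frame).
#' @export
compensate <- function(stream, cal) {
  stopifnot(inherits(cal, "calibration_params"))
  if (imu_frame(stream) != "sensor")
    stop("compensate: stream must be in the sensor frame")
  n <- nrow(stream)
  Mg <- diag(3) + cal$gyro_scale + cal$gyro_nonorth
  Ma <- diag(3) + cal$accel_scale + cal$accel_nonorth
  g_true <- t(solve(Mg, t(imu_gyro(stream) -
                            matrix(cal$gyro_bias, n, 3, byrow = TRUE))))
  a_true <- t(solve(Ma, t(imu_accel(stream) -
                            matrix(cal$accel_bias, n, 3, byrow = TRUE))))
  imu_replace(stream, gyro = g_true, accel = a_true)
}

#' Read / write the package's IMU CSV dialect
#'
#' Header `t,gx,gy,gz,ax,ay,az`, SI units (seconds, rad/s, m/s^2), `.`
#' decimal, UTF-8. `gyro_unit = "deg/s"` converts angular rates to rad/s on
#' ingest.
#'
#' @param path File path.
#' @param frame Frame tag to attach on read.
#' @param rate_hz Nominal sampling rate.
#' @param gyro_unit `"rad/s"` (default) or `"deg/s"`.
#' @return [read_imu_csv()] returns an `imu_stream`; [write_imu_csv()]
#'   returns `path` invisibly.
#' @export
read_imu_csv <- function(path, frame = "sensor", rate_hz = 200,
                         gyro_unit = c("rad/s", "deg/s")) {
  gyro_unit <- match.arg(gyro_unit)
  df <- utils::read.csv(path, colClasses = "numeric", fileEncoding = "UTF-8")
  need <- c("t", "gx", "gy", "gz", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop("read_imu_csv: header must contain t,gx,gy,gz,ax,ay,az")
  g <- as.matrix(df[, c("gx", "gy", "gz")])
  if (gyro_unit == "deg/s") g <- g * pi / 180
  imu_stream(df$t, g, as.matrix(df[, c("ax", "ay", "az")]),
             frame = frame, rate_hz = rate_hz)
}

#' @rdname read_imu_csv
#' @param stream `imu_stream` to write.
#' @export
write_imu_csv <- function(stream, path) {
  df <- as.data.frame(stream)
  # 12 significant digits keeps the read/write round trip well under 1e-9
  for (col in names(df)) df[[col]] <- formatC(df[[col]], format = "g", digits = 15)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read calibration parameters from a YAML config
#'
#' Expected key tree: `gyro: {bias, scale, nonorth}`, `accel: {bias, scale,
#' nonorth}`, `noise: {gyro_std, accel_std}`; matrices row-major length-9
#' vectors or nested lists; missing keys default to the identity calibration.
#'
#' @param path Path to a YAML file.
#' @return A [calibration_params()] object.
#' @export
read_calibration <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_mat <- function(x) {
    if (is.null(x)) return(matrix(0, 3, 3))
    m <- matrix(as.numeric(unlist(x)), 3, 3, byrow = TRUE)
    m
  }
  as_vec <- function(x) if (is.null(x)) c(0, 0, 0) else as.numeric(unlist(x))
  calibration_params(
    gyro_bias = as_vec(cfg$gyro$bias),
    accel_bias = as_vec(cfg$accel$bias),
    gyro_scale = as_mat(cfg$gyro$scale),
    accel_scale = as_mat(cfg$accel$scale),
    gyro_nonorth = as_mat(cfg$gyro$nonorth),
    accel_nonorth = as_mat(cfg$accel$nonorth),
    gyro_noise_std = as_vec(cfg$noise$gyro_std),
    accel_noise_std = as_vec(cfg$noise$accel_std))
}
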