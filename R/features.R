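# Per-window time-domain features.
#
# Schema (version 1), fixed order, axes x = right, y = forward, z = up:
#   accel_mean_[xyz], accel_var_[xyz], gyro_mean_[xyz], gyro_var_[xyz],
#   accel_sma_[xyz], pos_[xyz],
#   ratio_pos_[xyz], ratio_mean_[xyz], ratio_var_[xyz], ratio_sma_[xyz]
# 30 features. Variances are population (divide by N). SMA is the
# rectangular sum of |x| dt; position change is a double trapezoidal
# integration of the gravity-free user-frame acceleration from zero initial
# velocity/position with zero azimuth. Ratio features divide each per-axis
# value by the Euclidean norm of its axis triple, making them invariant to
# the strength of the motion.

FEATURE_SCHEMA_VERSION <- 1L

feature_names <- function() {
  ax <- c("x", "y", "z")
  c(paste0("accel_mean_", ax), paste0("accel_var_", ax),
    paste0("gyro_mean_", ax), paste0("gyro_var_", ax),
    paste0("accel_sma_", ax), paste0("pos_", ax),
    paste0("ratio_pos_", ax), paste0("ratio_mean_", ax),
    paste0("ratio_var_", ax), paste0("ratio_sma_", ax))
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Per-axis means and population variances of a window
#'
#' @param window A `segment_window`.
#' @return List with `accel_mean`, `accel_var`, `gyro_mean`, `gyro_var`
#'   (each length 3).
#' @export
mean_variance <- function(window) {
  a <- imu_accel(window$samples); g <- imu_gyro(window$samples)
  list(accel_mean = colMeans(a), accel_var = apply(a, 2, pop_var),
       gyro_mean = colMeans(g), gyro_var = apply(g, 2, pop_var))
}

#' Per-axis signal magnitude area of the window's acceleration
#'
#' Rectangular sum `sum(|a_i|) * dt` per axis; `dt` from the timestamps
#' (median), falling back to the nominal rate.
#'
#' @param window A `segment_window`.
#' @return Length-3 vector (m/s).
#' @export
sma <- function(window) {
  a <- imu_accel(window$samples)
  t <- window$samples$t
  dt <- if (length(t) > 1) stats::median(diff(t)) else 1 / attr(window$samples, "rate_hz")
  colSums(abs(a)) * dt
}

#' Short-horizon position change over the window
#'
#' Double trapezoidal integration of the gravity-free acceleration
#' `a_n = a_user - (0, 0, g)` with zero initial velocity and position and
#' zero azimuth. Only the 31-sample horizon is integrated — short enough
#' that MEMS integration drift is negligible.
#'
#' @param window A `segment_window` whose samples are in the user frame.
#' @param g Local gravity (m/s^2).
#' @return Length-3 displacement (m).
#' @export
position_change <- function(window, g = 9.80665) {
  a <- imu_accel(window$samples)
  t <- window$samples$t
  an <- sweep(a, 2, c(0, 0, g))
  v <- apply(an, 2, function(col) pracma::cumtrapz(t, col))
  p <- vapply(1:3, function(j) pracma::trapz(t, v[, j]), numeric(1))
  as.numeric(p)
}

#' Axis-ratio normalisation of a per-axis feature triple
#'
#' Each component divided by the Euclidean norm of the triple; the squared
#' ratios sum to one. A zero-norm triple yields `(0, 0, 0)` rather than an
#' error, so a degenerate window cannot kill a real-time stream.
#'
#' @param triple Length-3 numeric vector.
#' @return Length-3 vector of ratios.
#' @export
ratio_feature <- function(triple) {
  nrm <- sqrt(sum(triple^2))
  if (nrm == 0) return(c(0, 0, 0))
  triple / nrm
}

#' Assemble the full feature vector of a window
#'
#' Deterministic, fixed-order concatenation of means, variances, SMA,
#' position change and the four ratio triples (schema version 1; see
#' [feature_schema()]).
#'
#' @param window A user-frame `segment_window`.
#' @param g Local gravity (m/s^2).
#' @return Named numeric vector of length 30.
#' @export
build_feature_vector <- function(window, g = 9.80665) {
  mv <- mean_variance(window)
  s <- sma(window)
  p <- position_change(window, g)
  out <- c(mv$accel_mean, mv$accel_var, mv$gyro_mean, mv$gyro_var, s, p,
           ratio_feature(p), ratio_feature(mv$accel_mean),
           ratio_feature(mv$accel_var), ratio_feature(s))
  names(out) <- feature_names()
  out
}

#' Feature schema
#' @return List with `version` and ordered feature `names`.
#' @export
feature_schema <- function() {
  list(version = FEATURE_SCHEMA_VERSION, names = feature_names())
}

#' Feature matrix for a list of windows
#'
#' @param windows List of `segment_window` objects.
#' @param g Local gravity (m/s^2).
#' @return Numeric matrix, one row per window, columns per
#'   [feature_schema()].
#' @export
feature_matrix <- function(windows, g = 9.80665) {
  if (length(windows) == 0)
    return(matrix(numeric(0), 0, length(feature_names()),
                  dimnames = list(NULL, feature_names())))
  t(vapply(windows, build_feature_vector, numeric(length(feature_names())),
           g = g))
}
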