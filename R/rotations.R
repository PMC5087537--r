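# Rotation and quaternion utilities shared by the attitude filter, the
# user-frame projection and the synthetic generator.
#
# Conventions used throughout the package:
#   * user / navigation frame: Right (x) - Forward (y) - Up (z);
#   * C_b_n is the direction cosine matrix rotating body-frame vectors into
#     the navigation frame;
#   * Euler sequence C_b_n = Rz(yaw) %*% Rx(pitch) %*% Ry(roll), i.e. pitch
#     about the right axis, roll about the forward axis, yaw about up.
#     With this sequence the bottom row of C_b_n is independent of yaw, so
#     pitch/roll are exactly the gravity-observable part of the attitude.
#   * quaternions are length-4 numeric c(w, x, y, z), unit norm, mapping
#     body to navigation.

#' Elementary rotation matrices
#'
#' @param a Angle in radians.
#' @return A 3x3 rotation matrix about the x, y or z axis.
#' @keywords internal
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0,
           0, c_, -s_,
           0, s_, c_), 3, 3, byrow = TRUE)
}

#' @rdname elementary-rotations
rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, s_,
           0, 1, 0,
           -s_, 0, c_), 3, 3, byrow = TRUE)
}

#' @rdname elementary-rotations
rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, -s_, 0,
           s_, c_, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @param v Numeric length-3 vector.
#' @return 3x3 matrix M such that `M %*% w == v x w`.
#' @keywords internal
skew <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

#' Build a body-to-navigation DCM from Euler angles
#'
#' Sequence `Rz(yaw) %*% Rx(pitch) %*% Ry(roll)` in the Right-Forward-Up
#' frame convention.
#'
#' @param pitch,roll,yaw Angles in radians.
#' @return 3x3 rotation matrix.
#' @export
euler_to_dcm <- function(pitch, roll, yaw = 0) {
  rot_z(yaw) %*% rot_x(pitch) %*% rot_y(roll)
}

#' Extract Euler angles from a body-to-navigation DCM
#'
#' Inverse of [euler_to_dcm()]; pitch is recovered from `C[3, 2]`, roll from
#' `atan2(-C[3, 1], C[3, 3])`, yaw from `atan2(-C[1, 2], C[2, 2])`.
#'
#' @param C 3x3 rotation matrix (body to navigation).
#' @return Named numeric vector `c(pitch, roll, yaw)` in radians.
#' @export
dcm_to_euler <- function(C) {
  c(pitch = asin(max(-1, min(1, C[3, 2]))),
    roll = atan2(-C[3, 1], C[3, 3]),
    yaw = atan2(-C[1, 2], C[2, 2]))
}

# quaternion product (Hamilton convention, w first)
quat_mul <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

# rotation-vector (axis * angle, rad) -> quaternion
quat_from_rotvec <- function(rv) {
  ang <- sqrt(sum(rv^2))
  if (ang < 1e-12) {
    quat_normalize(c(1, rv / 2))
  } else {
    c(cos(ang / 2), sin(ang / 2) * rv / ang)
  }
}

# quaternion (body->nav) -> DCM
quat_to_dcm <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

dcm_to_quat <- function(C) {
  tr <- C[1, 1] + C[2, 2] + C[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (C[3, 2] - C[2, 3]) / s,
           (C[1, 3] - C[3, 1]) / s,
           (C[2, 1] - C[1, 2]) / s)
  } else {
    i <- which.max(c(C[1, 1], C[2, 2], C[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + C[1, 1] - C[2, 2] - C[3, 3]) * 2
      q <- c((C[3, 2] - C[2, 3]) / s, 0.25 * s,
             (C[1, 2] + C[2, 1]) / s, (C[1, 3] + C[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + C[2, 2] - C[1, 1] - C[3, 3]) * 2
      q <- c((C[1, 3] - C[3, 1]) / s, (C[1, 2] + C[2, 1]) / s,
             0.25 * s, (C[2, 3] + C[3, 2]) / s)
    } else {
      s <- sqrt(1 + C[3, 3] - C[1, 1] - C[2, 2]) * 2
      q <- c((C[2, 1] - C[1, 2]) / s, (C[1, 3] + C[3, 1]) / s,
             (C[2, 3] + C[3, 2]) / s, 0.25 * s)
    }
  }
  quat_normalize(q)
}
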