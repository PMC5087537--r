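# Synthetic gait-IMU generator.
#
# A step cycle has four phases — stance, push-off, swing, heel-strike — and
# is built in the user frame from smooth displacement profiles, so the
# signal is physically consistent by construction (zero net velocity per
# cycle, foot attitude and gyro agree exactly):
#
#   * horizontal travel along the motion's direction vector follows the
#     smooth-step s(u) = L * (u - sin(2*pi*u)/(2*pi)) over the movement
#     interval (push-off + swing), giving a sharp acceleration peak in the
#     push-off phase and a deceleration peak near landing;
#   * vertical lift follows z(u) = h * sin(pi*u)^4 (up and back down, zero
#     net, acceleration continuous at the boundaries);
#   * a short biphasic (zero-mean) impact pulse marks heel strike;
#   * the foot pitches about the user's right axis by theta(u) =
#     Theta * sin(pi*u)^2 during movement; the body attitude is
#     C_b_u(t) = Rx(theta(t)) %*% R_mis with R_mis the constant mounting
#     misalignment, and gyro/accelerometer outputs are the exact body-frame
#     projections of the true kinematics.
#
# Amplitudes scale linearly with a per-step `strength` multiplier; all
# shape constants live in `synthetic_defaults()`.

#' Shape constants of the synthetic gait model
#'
#' Amplitudes at `strength = 1`: step length (m), foot lift (m), jump lift
#' (m), heel-strike impact amplitude (m/s^2), impact duration (s), swing
#' pitch amplitude (rad) and the jump's reduced pitch amplitude.
#' @return Named list of constants.
#' @export
synthetic_defaults <- function() {
  list(step_length = 0.40,     # horizontal travel of one step
       foot_lift = 0.05,       # vertical lift during a step
       jump_lift = 0.12,       # vertical lift of a jump
       jump_drift = 0.02,      # residual horizontal travel of a jump
       impact_amp = 5,         # heel-strike biphasic pulse (m/s^2)
       impact_dur = 0.05,      # heel-strike pulse duration (s)
       impact_delay = 0.02,    # pulse onset after swing end (s)
       pitch_amp = 0.35,       # swing pitch excursion (rad)
       jump_pitch_amp = 0.10)
}

#' Direction vector of a motion in the user frame
#'
#' left -> -x, right -> +x, forward -> +y, backward -> -y, jump -> +z.
#' @param motion One of [MOTION_LABELS].
#' @return Unit 3-vector.
#' @export
motion_direction <- function(motion) {
  switch(match.arg(motion, MOTION_LABELS),
         jump = c(0, 0, 1), left = c(-1, 0, 0), right = c(1, 0, 0),
         forward = c(0, 1, 0), backward = c(0, -1, 0))
}

#' Motion profile for the synthetic generator
#'
#' @param motion One of [MOTION_LABELS].
#' @param strength Amplitude multiplier (1 = nominal).
#' @param cycle_duration Gait-cycle duration (s).
#' @param phase_fractions Named fractions `(stance, push_off, swing,
#'   heel_strike)`; positive, summing to 1.
#' @param misalignment_deg Mounting offset `c(pitch, roll)` in degrees.
#' @param gyro_bias Constant gyro bias (rad/s).
#' @param accel_noise_std,gyro_noise_std Per-sample Gaussian noise sd
#'   (scalar or length 3).
#' @param g Local gravity (m/s^2).
#' @param rate_hz Sampling rate.
#' @return Object of class `motion_profile`.
#' @export
motion_profile <- function(motion, strength = 1, cycle_duration = 0.7,
                           phase_fractions = c(stance = 0.25, push_off = 0.25,
                                               swing = 0.30, heel_strike = 0.20),
                           misalignment_deg = c(pitch = 0, roll = 0),
                           gyro_bias = c(0, 0, 0),
                           accel_noise_std = 0.05, gyro_noise_std = 0.01,
                           g = 9.80665, rate_hz = 200) {
  motion <- match.arg(motion, MOTION_LABELS)
  stopifnot(all(phase_fractions > 0),
            abs(sum(phase_fractions) - 1) < 1e-9,
            strength > 0, cycle_duration > 0)
  structure(list(motion = motion, strength = strength,
                 cycle_duration = cycle_duration,
                 phase_fractions = phase_fractions,
                 direction = motion_direction(motion),
                 misalignment_deg = misalignment_deg,
                 gyro_bias = as.numeric(gyro_bias),
                 accel_noise_std = rep(as.numeric(accel_noise_std), length.out = 3),
                 gyro_noise_std = rep(as.numeric(gyro_noise_std), length.out = 3),
                 g = g, rate_hz = rate_hz),
            class = "motion_profile")
}

# user-frame kinematics of one cycle on a local time grid starting at 0:
# returns motion acceleration (without gravity), pitch angle/rate series,
# phase boundaries and net displacement
build_cycle <- function(profile) {
  k <- synthetic_defaults()
  rate <- profile$rate_hz
  n <- round(profile$cycle_duration * rate)
  tt <- (seq_len(n) - 1) / rate
  pf <- profile$phase_fractions
  t1 <- pf[["stance"]] * profile$cycle_duration
  t2 <- t1 + pf[["push_off"]] * profile$cycle_duration
  t3 <- t2 + pf[["swing"]] * profile$cycle_duration
  Tm <- t3 - t1
  jump <- profile$motion == "jump"
  L <- profile$strength * if (jump) k$jump_drift else k$step_length
  h <- profile$strength * if (jump) k$jump_lift else k$foot_lift
  Theta <- profile$strength * if (jump) k$jump_pitch_amp else k$pitch_amp
  dvec <- profile$direction
  d_h <- if (jump) c(0, 1, 0) else dvec   # jump drifts slightly forward

  a <- matrix(0, n, 3)
  theta <- numeric(n); theta_dot <- numeric(n)
  mv <- tt >= t1 & tt < t3
  u <- (tt[mv] - t1) / Tm
  a_h <- L * 2 * pi * sin(2 * pi * u) / Tm^2
  s2 <- sin(pi * u)^2; c2 <- cos(pi * u)^2
  a_z <- h * 4 * pi^2 * (3 * s2 * c2 - s2^2) / Tm^2
  a[mv, ] <- outer(a_h, d_h)
  a[mv, 3] <- a[mv, 3] + a_z
  theta[mv] <- Theta * s2
  theta_dot[mv] <- Theta * pi * sin(2 * pi * u) / Tm
  # biphasic heel-strike pulse (zero net velocity)
  ti <- t3 + k$impact_delay
  im <- tt >= ti & tt < ti + k$impact_dur
  if (any(im)) {
    tau <- (tt[im] - ti) / k$impact_dur
    a[im, 3] <- a[im, 3] + profile$strength * k$impact_amp * sin(2 * pi * tau)
  }
  list(n = n, accel = a, theta = theta, theta_dot = theta_dot,
       bounds = c(stance_end = t1, push_off_end = t2, swing_end = t3),
       disp = L * d_h, lift = h)
}

# rotate user-frame kinematics into the (possibly misaligned, pitching)
# sensor frame and apply the sensor-error model
user_to_sensor_stream <- function(t, f_u, w_u, theta, profile, noise = TRUE) {
  Rm <- euler_to_dcm(profile$misalignment_deg[[1]] * pi / 180,
                     profile$misalignment_deg[[2]] * pi / 180, 0)
  ct <- cos(theta); st <- sin(theta)
  # v_b = t(Rm) %*% Rx(-theta) %*% v_u, vectorised over rows
  rot_rows <- function(V) {
    W <- cbind(V[, 1], ct * V[, 2] + st * V[, 3], -st * V[, 2] + ct * V[, 3])
    W %*% Rm
  }
  clean <- imu_stream(t, rot_rows(w_u), rot_rows(f_u),
                      frame = "sensor", rate_hz = profile$rate_hz)
  cal <- calibration_params(gyro_bias = profile$gyro_bias,
                            gyro_noise_std = profile$gyro_noise_std,
                            accel_noise_std = profile$accel_noise_std)
  apply_sensor_errors(clean, cal, noise = noise)
}

#' Simulate one labelled step
#'
#' One gait cycle preceded by `lead_in_s` of static stance (enough for the
#' attitude filter's leveling window). Deterministic given `seed`.
#'
#' @param profile A [motion_profile()].
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param lead_in_s Static lead-in (s).
#' @param noise Add measurement noise (default `TRUE`).
#' @return A `labelled_stream`: list with `stream` (sensor-frame measured
#'   `imu_stream`), `clean_user` (noiseless user-frame truth), `truth`
#'   (one row per step: motion, phase boundaries, smoothed-norm push-off
#'   peak time, net displacement, lift) and `profile`.
#' @export
simulate_step <- function(profile, seed = NULL, lead_in_s = 1, noise = TRUE) {
  simulate_session(profile$motion, base = profile, seed = seed,
                   lead_in_s = lead_in_s, noise = noise,
                   strength_range = c(1, 1), cycle_range = c(1, 1))
}

#' Simulate a labelled multi-step session
#'
#' Concatenates one cycle per requested motion with inter-step stance
#' padding, jittering per-step strength and cycle duration to emulate
#' different users' strengths, frequencies and amplitudes. The mounting
#' misalignment and gyro bias of `base` apply to the whole session (one
#' wearer, one mounting).
#'
#' @param motions Character vector of step motions, in order.
#' @param base A [motion_profile()] supplying everything except the motion;
#'   its `strength` multiplies the sampled per-step strengths.
#' @param strength_range Per-step strength sampled uniformly from this
#'   range (times `base$strength`).
#' @param cycle_range Per-step cycle-duration multiplier range.
#' @param pad_s Inter-step stance padding (s).
#' @param lead_in_s Static lead-in before the first step (s).
#' @param seed Integer seed; the session is a pure function of it.
#' @param noise Add measurement noise.
#' @return A `labelled_stream` (see [simulate_step()]) with one truth row
#'   per step.
#' @export
simulate_session <- function(motions, base = motion_profile("forward"),
                             strength_range = c(0.5, 1.5),
                             cycle_range = c(0.6, 0.9),
                             pad_s = 0.3, lead_in_s = 1,
                             seed = NULL, noise = TRUE) {
  stopifnot(length(motions) >= 1, all(motions %in% MOTION_LABELS))
  if (!is.null(seed)) set.seed(seed)
  rate <- base$rate_hz
  strengths <- stats::runif(length(motions), strength_range[1], strength_range[2]) *
    base$strength
  cycles <- stats::runif(length(motions), cycle_range[1], cycle_range[2]) *
    base$cycle_duration

  segs_a <- list(); segs_th <- list(); segs_thd <- list()
  truth <- list()
  n_lead <- round(lead_in_s * rate)
  n_pad <- round(pad_s * rate)
  zeros <- function(n) list(a = matrix(0, n, 3), th = numeric(n), thd = numeric(n))
  push <- function(seg) {
    segs_a[[length(segs_a) + 1]] <<- seg$a
    segs_th[[length(segs_th) + 1]] <<- seg$th
    segs_thd[[length(segs_thd) + 1]] <<- seg$thd
  }
  push(zeros(n_lead))
  offset <- n_lead
  for (i in seq_along(motions)) {
    pr <- motion_profile(motions[i], strength = strengths[i],
                         cycle_duration = cycles[i],
                         phase_fractions = base$phase_fractions,
                         misalignment_deg = base$misalignment_deg,
                         gyro_bias = base$gyro_bias,
                         accel_noise_std = base$accel_noise_std,
                         gyro_noise_std = base$gyro_noise_std,
                         g = base$g, rate_hz = rate)
    cyc <- build_cycle(pr)
    t0 <- offset / rate
    truth[[i]] <- data.frame(step = i, motion = motions[i],
                             strength = strengths[i],
                             t_start = t0,
                             stance_end = t0 + cyc$bounds[["stance_end"]],
                             push_off_end = t0 + cyc$bounds[["push_off_end"]],
                             swing_end = t0 + cyc$bounds[["swing_end"]],
                             t_end = t0 + cyc$n / rate,
                             peak_time = NA_real_,
                             disp_x = cyc$disp[1], disp_y = cyc$disp[2],
                             disp_z = cyc$disp[3], lift = cyc$lift)
    push(list(a = cyc$accel, th = cyc$theta, thd = cyc$theta_dot))
    offset <- offset + cyc$n
    if (i < length(motions)) {
      push(zeros(n_pad))
      offset <- offset + n_pad
    }
  }
  a_mot <- do.call(rbind, segs_a)
  theta <- unlist(segs_th); theta_dot <- unlist(segs_thd)
  n <- nrow(a_mot)
  t <- (seq_len(n) - 1) / rate
  f_u <- a_mot + matrix(c(0, 0, base$g), n, 3, byrow = TRUE)
  w_u <- cbind(theta_dot, 0, 0)
  truth <- do.call(rbind, truth)

  clean_user <- imu_stream(t, w_u, f_u, frame = "user", rate_hz = rate)
  # ground-truth push-off peak: apex of the causally smoothed noiseless
  # norm within each step's push-off phase (the detector's own definition
  # of a peak, free of noise and misalignment)
  sm <- smooth_norm(clean_user, smoother_config())
  for (i in seq_len(nrow(truth))) {
    rows <- which(t >= truth$stance_end[i] & t < truth$push_off_end[i])
    truth$peak_time[i] <- t[rows[which.max(sm[rows])]]
  }
  stream <- user_to_sensor_stream(t, f_u, w_u, theta, base, noise = noise)
  structure(list(stream = stream, clean_user = clean_user, truth = truth,
                 profile = base),
            class = "labelled_stream")
}

#' Simulate a static (stance-only) capture
#'
#' @param duration_s Length (s).
#' @param profile A [motion_profile()] supplying mounting, bias, noise and
#'   rate (its motion is ignored).
#' @param seed Integer seed.
#' @param noise Add measurement noise.
#' @return A sensor-frame `imu_stream`.
#' @export
simulate_static <- function(duration_s = 5, profile = motion_profile("forward"),
                            seed = NULL, noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  rate <- profile$rate_hz
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  f_u <- matrix(c(0, 0, profile$g), n, 3, byrow = TRUE)
  user_to_sensor_stream(t, f_u, matrix(0, n, 3), numeric(n), profile,
                        noise = noise)
}

#' Simulate a multi-wearer study
#'
#' One session per wearer, each with its own mounting misalignment, gyro
#' bias and strength habit, and a shuffled motion sequence with the
#' requested per-motion counts — the study design behind the end-to-end
#' benchmark.
#'
#' @param n_users Number of wearers.
#' @param steps_per_motion Steps of each motion per wearer.
#' @param seed Integer seed.
#' @param misalignment_max_deg Per-user pitch/roll mounting offsets are
#'   drawn uniformly from ± this bound.
#' @param bias_max Per-user gyro-bias components drawn from ± this bound
#'   (rad/s).
#' @param ... Further arguments to [motion_profile()] (noise, rate, ...).
#' @return List of `labelled_stream` sessions, one per user.
#' @export
simulate_study <- function(n_users = 5, steps_per_motion = 10, seed = 1,
                           misalignment_max_deg = 20, bias_max = 0.02, ...) {
  set.seed(seed)
  lapply(seq_len(n_users), function(u) {
    mis <- stats::runif(2, -misalignment_max_deg, misalignment_max_deg)
    bias <- stats::runif(3, -bias_max, bias_max)
    motions <- sample(rep(MOTION_LABELS, steps_per_motion))
    base <- motion_profile("forward", misalignment_deg = mis,
                           gyro_bias = bias, ...)
    simulate_session(motions, base = base,
                     seed = sample.int(.Machine$integer.max, 1))
  })
}

#' Write a small fixture suite of CSV streams
#'
#' Emits a static capture, one single-step stream per motion, and a mixed
#' session, each as the package's CSV dialect plus a JSON ground-truth
#' sidecar.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Character vector of the files written.
#' @export
make_fixture_suite <- function(dir = tempfile("fixtures"), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- character(0)
  emit <- function(stream, truth, stem) {
    csv <- file.path(dir, paste0(stem, ".csv"))
    write_imu_csv(stream, csv)
    files <<- c(files, csv)
    if (!is.null(truth)) {
      js <- file.path(dir, paste0(stem, "_truth.json"))
      jsonlite::write_json(truth, js, digits = NA)
      files <<- c(files, js)
    }
  }
  base <- motion_profile("forward", misalignment_deg = c(10, -5),
                         gyro_bias = c(0.01, -0.005, 0.008))
  emit(simulate_static(2, base, seed = seed), NULL, "static")
  for (m in MOTION_LABELS) {
    ls_ <- simulate_session(m, base = base, seed = seed + match(m, MOTION_LABELS))
    emit(ls_$stream, ls_$truth, paste0("step_", m))
  }
  ses <- simulate_session(sample(rep(MOTION_LABELS, 2)), base = base,
                          seed = seed + 100)
  emit(ses$stream, ses$truth, "session_mixed")
  files
}
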