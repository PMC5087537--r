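# Push-off peak detection and fixed-window segmentation.
#
# One gait cycle shows two peaks of the smoothed acceleration norm: one in
# the push-off phase (foot leaving the ground) and one at heel strike. The
# push-off peak is the segmentation trigger; the classified window is 31
# samples: 20 before the peak, the peak, and 10 after. At 200 Hz the window
# spans 30/200 = 0.15 s, which bounds the decision latency.

#' Smoother / peak-detector configuration
#'
#' @param window_n Moving-average length N (samples). The smoothed value at
#'   sample i is the mean of the last N norm values ending at i (causal);
#'   the first N-1 samples average the available prefix.
#' @param min_peak_height Minimum smoothed-norm height for an accepted peak
#'   (m/s^2). Default `g + 2`: well above the at-rest norm, below any
#'   deliberate step's push-off.
#' @param refractory Minimum sample separation between accepted peaks;
#'   suppresses the deceleration and heel-strike peaks of the same cycle
#'   while admitting the next step's push-off. Default 90 samples = 0.45 s
#'   at 200 Hz, just under the fastest plausible step period.
#' @return Object of class `smoother_config`.
#' @export
smoother_config <- function(window_n = 10,
                            min_peak_height = 9.80665 + 2,
                            refractory = 90) {
  stopifnot(window_n >= 1, refractory >= 0)
  structure(list(window_n = as.integer(window_n),
                 min_peak_height = min_peak_height,
                 refractory = as.integer(refractory)),
            class = "smoother_config")
}

#' Causally smoothed acceleration norm
#'
#' @param stream A user-frame `imu_stream` (or any `imu_stream`).
#' @param cfg A [smoother_config()].
#' @return Numeric vector, one smoothed norm value per sample.
#' @export
smooth_norm <- function(stream, cfg = smoother_config()) {
  nrm <- sqrt(stream$ax^2 + stream$ay^2 + stream$az^2)
  running_mean(nrm, cfg$window_n)
}

# trailing mean of the last n values (prefix-partial at the start)
running_mean <- function(x, n) {
  cs <- cumsum(x)
  len <- length(x)
  i <- seq_len(len)
  lag <- pmin(i, n)
  (cs - c(rep(0, min(n, len)), cs[seq_len(max(0, len - n))])) / lag
}

#' Detect push-off peaks on a smoothed series
#'
#' A peak is a sample with `s[i-1] < s[i] >= s[i+1]`, height at least
#' `min_peak_height`, and at least `refractory` samples after the previously
#' accepted peak. A peak at index i is decidable one sample later, so the
#' rule is directly usable online.
#'
#' @param smoothed Numeric series from [smooth_norm()].
#' @param cfg A [smoother_config()].
#' @return Integer vector of peak indices (1-based), possibly empty.
#' @export
detect_peaks <- function(smoothed, cfg = smoother_config()) {
  n <- length(smoothed)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  cand <- i[smoothed[i - 1] < smoothed[i] &
              smoothed[i] >= smoothed[i + 1] &
              smoothed[i] >= cfg$min_peak_height]
  if (length(cand) == 0) return(integer(0))
  keep <- integer(0)
  last <- -Inf
  for (idx in cand) {
    if (idx - last >= cfg$refractory) {
      keep <- c(keep, idx)
      last <- idx
    }
  }
  keep
}

#' Cut the 31-sample classification window around a peak
#'
#' @param stream A user-frame `imu_stream`.
#' @param peak_idx Index (1-based) of the accepted peak in `stream`.
#' @param attitude_at_peak Optional 3x3 rotation snapshot stored with the
#'   window.
#' @return A `segment_window`: list with the 31-row `samples` stream slice,
#'   `peak_index_local` (always 21, 1-based: 20 before + peak + 10 after),
#'   `peak_time`, `peak_index` and `attitude_at_peak`; or `NULL` with a
#'   warning when fewer than 20 samples precede or 10 follow the peak.
#' @export
extract_window <- function(stream, peak_idx, attitude_at_peak = NULL) {
  if (peak_idx - 20 < 1 || peak_idx + 10 > nrow(stream)) {
    warning("extract_window: insufficient history/future around peak; window dropped")
    return(NULL)
  }
  rows <- (peak_idx - 20):(peak_idx + 10)
  samples <- imu_stream(stream$t[rows],
                        imu_gyro(stream)[rows, ], imu_accel(stream)[rows, ],
                        frame = imu_frame(stream),
                        rate_hz = attr(stream, "rate_hz"))
  structure(list(samples = samples,
                 peak_index_local = 21L,
                 peak_index = as.integer(peak_idx),
                 peak_time = stream$t[peak_idx],
                 attitude_at_peak = attitude_at_peak),
            class = "segment_window")
}

#' Segment a stream into classification windows
#'
#' Smooths, detects push-off peaks and cuts one 31-sample window per
#' accepted peak. `mode = "streaming"` replays the stream one sample at a
#' time through the same online rules (a peak is accepted one sample after
#' its apex, the window emitted once 10 post-peak samples exist) and is
#' guaranteed to produce the identical window set.
#'
#' @param stream A user-frame `imu_stream`.
#' @param cfg A [smoother_config()].
#' @param mode `"offline"` (vectorised) or `"streaming"` (sample-by-sample).
#' @return List with `windows` (list of `segment_window`), `peaks` (indices)
#'   and `smoothed` (the smoothed norm series).
#' @export
segment_stream <- function(stream, cfg = smoother_config(),
                           mode = c("offline", "streaming")) {
  mode <- match.arg(mode)
  if (mode == "offline") {
    sm <- smooth_norm(stream, cfg)
    peaks <- detect_peaks(sm, cfg)
  } else {
    res <- segment_streaming(stream, cfg)
    sm <- res$smoothed
    peaks <- res$peaks
  }
  windows <- list()
  kept <- integer(0)
  for (p in peaks) {
    w <- withCallingHandlers(extract_window(stream, p),
                             warning = function(cnd) invokeRestart("muffleWarning"))
    if (!is.null(w)) {
      windows[[length(windows) + 1]] <- w
      kept <- c(kept, p)
    }
  }
  list(windows = windows, peaks = peaks, windowed_peaks = kept, smoothed = sm)
}

# sample-at-a-time replay of smoothing + peak logic; state is exactly what
# an online implementation would keep (running sum, last two smoothed
# values, last accepted peak index)
segment_streaming <- function(stream, cfg) {
  nrm <- sqrt(stream$ax^2 + stream$ay^2 + stream$az^2)
  n <- length(nrm)
  N <- cfg$window_n
  buf <- numeric(0)
  sm <- numeric(n)
  peaks <- integer(0)
  last <- -Inf
  s_prev2 <- NA_real_; s_prev <- NA_real_
  for (i in seq_len(n)) {
    buf <- c(buf, nrm[i])
    if (length(buf) > N) buf <- buf[-1]
    sm[i] <- mean(buf)
    # the decision made at sample i concerns sample i-1
    if (i >= 3 && !is.na(s_prev2)) {
      if (s_prev2 < s_prev && s_prev >= sm[i] &&
          s_prev >= cfg$min_peak_height && (i - 1) - last >= cfg$refractory) {
        peaks <- c(peaks, i - 1L)
        last <- i - 1L
      }
    }
    s_prev2 <- s_prev
    s_prev <- sm[i]
  }
  list(peaks = peaks, smoothed = sm)
}
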