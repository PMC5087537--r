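# End-to-end wiring: compensate -> attitude filter -> user-frame projection
# -> segmentation -> features -> per-window classification, plus the window
# labelling used to train from synthetic ground truth.

#' Pipeline configuration
#'
#' One tree holding every stage's configuration. Unknown keys are rejected.
#'
#' @param cal A [calibration_params()] object.
#' @param filter A [filter_config()].
#' @param smoother A [smoother_config()].
#' @param g Local gravity (m/s^2), shared by features.
#' @return Object of class `pipeline_config` (versioned).
#' @export
pipeline_config <- function(cal = calibration_params(),
                            filter = filter_config(),
                            smoother = smoother_config(),
                            g = 9.80665) {
  structure(list(version = 1L, cal = cal, filter = filter,
                 smoother = smoother, g = g),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `calibration`, `filter`, `smoother`, `g`; unknown keys
#' are an error. Each block holds arguments of the corresponding
#' constructor.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("calibration", "filter", "smoother", "g")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("read_pipeline_config: unknown keys: ",
                        paste(bad, collapse = ", "))
  cal <- if (is.null(cfg$calibration)) calibration_params()
         else do.call(calibration_params, cfg$calibration)
  flt <- if (is.null(cfg$filter)) filter_config()
         else do.call(filter_config, cfg$filter)
  smo <- if (is.null(cfg$smoother)) smoother_config()
         else do.call(smoother_config, cfg$smoother)
  pipeline_config(cal, flt, smo, g = cfg$g %||% 9.80665)
}

#' Segment a raw sensor stream into user-frame feature windows
#'
#' Runs compensation, the attitude filter, user-frame projection and
#' segmentation, and extracts the feature matrix.
#'
#' @param stream Raw sensor-frame `imu_stream`.
#' @param config A [pipeline_config()].
#' @param mode Segmentation mode (`"offline"` or `"streaming"`).
#' @return List with `windows`, `features` (matrix), `peaks`,
#'   `user_stream` and `track`.
#' @export
collect_windows <- function(stream, config = pipeline_config(),
                            mode = "offline") {
  comp <- compensate(stream, config$cal)
  track <- run_attitude_filter(comp, config$filter)
  user <- to_user_frame(comp, track)
  seg <- segment_stream(user, config$smoother, mode = mode)
  list(windows = seg$windows, features = feature_matrix(seg$windows, config$g),
       peaks = seg$peaks, user_stream = user, track = track)
}

#' Label detected windows against synthetic ground truth
#'
#' Matches each detected window to the nearest ground-truth push-off peak
#' and labels it with that step's motion; windows farther than
#' `max_offset` samples from any truth peak stay unlabelled (`NA`).
#'
#' @param windows List of `segment_window` objects.
#' @param truth Truth data frame of a `labelled_stream`.
#' @param rate_hz Sampling rate.
#' @param max_offset Matching tolerance in samples.
#' @return Data frame with `window`, `step`, `motion`, `offset_samples`.
#' @export
label_windows <- function(windows, truth, rate_hz = 200, max_offset = 5) {
  if (length(windows) == 0)
    return(data.frame(window = integer(0), step = integer(0),
                      motion = character(0), offset_samples = numeric(0)))
  do.call(rbind, lapply(seq_along(windows), function(i) {
    dt_samp <- (windows[[i]]$peak_time - truth$peak_time) * rate_hz
    j <- which.min(abs(dt_samp))
    hit <- abs(dt_samp[j]) <= max_offset
    data.frame(window = i,
               step = if (hit) truth$step[j] else NA_integer_,
               motion = if (hit) truth$motion[j] else NA_character_,
               offset_samples = dt_samp[j])
  }))
}

#' Run the full identification pipeline over a stream
#'
#' Emits one arbitrated motion event per detected push-off peak. The
#' decision latency is fixed by construction: 10 samples after the peak
#' (the tail of the 31-sample window) plus the smoother's group delay.
#'
#' @param stream Raw sensor-frame `imu_stream`.
#' @param bank A trained `classifier_bank`.
#' @param config A [pipeline_config()].
#' @param mode Segmentation mode.
#' @return Event log data frame: `t` (peak time), `label`, `score`,
#'   `latency_samples`.
#' @export
run_pipeline <- function(stream, bank, config = pipeline_config(),
                         mode = "offline") {
  cw <- collect_windows(stream, config, mode = mode)
  if (length(cw$windows) == 0)
    return(data.frame(t = numeric(0), label = character(0),
                      score = numeric(0), latency_samples = integer(0)))
  pred <- predict_bank(bank, cw$features)
  data.frame(t = vapply(cw$windows, `[[`, numeric(1), "peak_time"),
             label = as.character(pred$label),
             score = pred$score,
             latency_samples = 10L + config$smoother$window_n)
}
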