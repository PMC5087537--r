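# Shared fixtures, built in code. Heavier objects are memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# a 31-sample user-frame window built directly from accel/gyro matrices
make_test_window <- function(accel, gyro = matrix(0, 31, 3), rate_hz = 200) {
  t <- (0:30) / rate_hz
  s <- imu_stream(t, gyro, accel, frame = "user", rate_hz = rate_hz)
  extract_window(s, 21)
}

# constant-accel window (one row repeated)
const_window <- function(a, g = matrix(0, 31, 3)) {
  make_test_window(matrix(rep(a, each = 31), 31, 3), g)
}

# small mixed session with a modest mounting offset and gyro bias
small_session <- function() {
  memo("small_session", {
    base <- motion_profile("forward", misalignment_deg = c(12, -6),
                           gyro_bias = c(0.01, -0.005, 0.008))
    set.seed(101)
    simulate_session(sample(rep(MOTION_LABELS, 3)), base = base, seed = 202)
  })
}

# windows + labels extracted from clean user-frame streams (no filter),
# n_per steps of every motion; fast path for feature-level properties
clean_motion_windows <- function(n_per, seed = 77) {
  key <- paste0("clean_windows_", n_per, "_", seed)
  memo(key, {
    ses <- simulate_session(rep(MOTION_LABELS, n_per),
                            base = motion_profile("forward"),
                            seed = seed, noise = FALSE)
    seg <- segment_stream(ses$clean_user)
    lw <- label_windows(seg$windows, ses$truth)
    list(windows = seg$windows, labels = lw$motion, truth = ses$truth,
         features = feature_matrix(seg$windows))
  })
}

# trained bank + features from a small multi-user study (through the full
# pipeline); used by classify/pipeline tests
small_corpus <- function() {
  memo("small_corpus", {
    sessions <- simulate_study(n_users = 3, steps_per_motion = 6, seed = 31)
    feats <- list(); labs <- list()
    for (s in sessions) {
      cw <- collect_windows(s$stream)
      lw <- label_windows(cw$windows, s$truth)
      ok <- !is.na(lw$motion)
      feats[[length(feats) + 1]] <- cw$features[ok, , drop = FALSE]
      labs[[length(labs) + 1]] <- lw$motion[ok]
    }
    list(x = do.call(rbind, feats), y = unlist(labs))
  })
}
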