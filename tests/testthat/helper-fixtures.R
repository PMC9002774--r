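# Shared fixtures, built once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small inertial-only cohort, preprocessed and windowed, with features
small_cohort_fit_data <- function() {
  cached("small_cohort", function() {
    p <- cohort_params(n_subjects = 4, tasks_per_subject = 1,
                       task_duration_s = 60,
                       modalities = c("tibia_acc", "tibia_gyro"), seed = 7)
    co <- simulate_cohort(p)
    ann <- suppressMessages(exclude_short_episodes(co$annotations))
    wl <- list(); fl <- list()
    for (rec in co$recordings) {
      r <- preprocess_recording(rec)
      w <- segment_windows(r, ann)
      f <- extract_features(r, w, sensors = "tibia")
      wl[[length(wl) + 1]] <- w
      fl[[length(fl) + 1]] <- f$x
    }
    W <- do.call(rbind, wl)
    attr(W, "fs") <- 500; attr(W, "window_len_s") <- 3; attr(W, "overlap") <- 0.9
    list(windows = W, x = do.call(rbind, fl), annotations = ann, params = p)
  })
}

# one short multi-modal recording (all six modalities), raw + processed
small_multimodal <- function() {
  cached("small_multimodal", function() {
    p <- cohort_params(n_subjects = 1, tasks_per_subject = 1,
                       task_duration_s = 12, fog_rate = 5, seed = 11)
    s <- simulate_subject(p, 1)
    list(raw = s$recordings[[1]],
         processed = preprocess_recording(s$recordings[[1]]),
         annotations = s$annotations, params = p)
  })
}

# a deterministic binary label vector and orthonormal helper for building
# features with exact correlations to the label
make_exact_r_feature <- function(y, r, seed = 1) {
  n <- length(y)
  yc <- (y - mean(y)) / sqrt(sum((y - mean(y))^2))
  z <- with_seed_test(seed, rnorm(n))
  z <- z - mean(z)
  z <- z - sum(z * yc) * yc          # orthogonal to centered y
  z <- z / sqrt(sum(z^2))
  as.vector(r * yc + sqrt(1 - r^2) * z)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# pure sinusoid helper
sine <- function(freq, fs, dur_s, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(0, dur_s - 1 / fs, by = 1 / fs) + phase)
}
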