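# Synthetic cohort generator: determinism, episode statistics, spectral
# structure of the simulated regimes.

test_that("parameter validation rejects degenerate settings", {
  expect_error(cohort_params(task_duration_s = -5), "positive")
  expect_error(cohort_params(fog_amplitude_ratio = 1.2), "0, 1")
  expect_error(cohort_params(episode_median_s = Inf), "positive")
})

test_that("fog_rate = 0 yields an all-walking recording with no annotations", {
  p <- cohort_params(n_subjects = 1, tasks_per_subject = 2, fog_rate = 0,
                     task_duration_s = 20,
                     modalities = c("tibia_acc", "sc"), seed = 2)
  s <- simulate_subject(p, 1)
  expect_equal(nrow(s$annotations), 0)
  expect_length(s$recordings, 2)
})

test_that("same (params, subject_index) is bit-reproducible", {
  p <- cohort_params(n_subjects = 2, tasks_per_subject = 1,
                     task_duration_s = 15,
                     modalities = c("tibia_acc", "eeg", "sc"), seed = 9)
  a <- simulate_subject(p, 2)
  b <- simulate_subject(p, 2)
  expect_identical(a, b)
})

test_that("cohort structure: counts and per-subject frequency sharing", {
  p <- cohort_params(n_subjects = 3, tasks_per_subject = 4,
                     task_duration_s = 10, fog_rate = 1,
                     modalities = "tibia_acc", seed = 4)
  co <- simulate_cohort(p)
  expect_length(co$recordings, 12)
  # per-subject cadence shared across tasks: dominant frequency of the raw
  # walking signal must agree between a subject's tasks
  dom_freq <- function(rec) {
    x <- rec$modalities$tibia_acc$samples[1, ]
    sp <- Mod(fft(x))^2
    f <- (seq_along(sp) - 1) * 100 / length(sp)
    keep <- f > 0.3 & f < 50
    f[keep][which.max(sp[keep])]
  }
  subj <- vapply(co$recordings, function(r) r$subject_id, "")
  for (s in unique(subj)) {
    doms <- vapply(co$recordings[subj == s], dom_freq, 0)
    expect_lt(max(doms) - min(doms), 0.21)  # same cadence, fft-bin jitter
  }
})

test_that("episode counts follow the Poisson arrival model", {
  # 2 episodes/min on a 120 s task: per-draw counts must lie in the central
  # 99% range of Poisson(4)
  lo <- qpois(0.005, 4); hi <- qpois(0.995, 4)
  p <- cohort_params(n_subjects = 1, tasks_per_subject = 1,
                     task_duration_s = 120, fog_rate = 2,
                     modalities = "tibia_acc")
  counts <- vapply(1:200, function(i) {
    pp <- p; pp$seed <- i
    nrow(simulate_subject(pp, 1)$annotations)
  }, 0)
  expect_true(all(counts >= lo & counts <= hi))
  # mean should sit near the nominal rate (placement drops are rare)
  expect_gt(mean(counts), 4 - 3 * sqrt(4 / 200) - 0.4)
})

test_that("episode durations match the log-normal clinical anchors", {
  p <- cohort_params(n_subjects = 1, tasks_per_subject = 1,
                     task_duration_s = 600, fog_rate = 1,
                     episode_median_s = 8, modalities = "tibia_acc")
  durs <- unlist(lapply(1:60, function(i) {
    pp <- p; pp$seed <- 1000 + i
    a <- simulate_subject(pp, 1)$annotations
    a$end_s - a$start_s
  }))
  expect_gt(length(durs), 500)
  durs <- durs[1:500]
  frac10 <- mean(durs < 10)
  expect_lt(abs(frac10 - plnorm(10, log(8), 1.1)), 0.10)
  # durations stay inside the truncation range
  expect_true(all(durs >= 1 & durs <= 200))
  # episodes are sorted and separated by the refractory gap within a task
})

test_that("episodes are non-overlapping, sorted, inside the recording", {
  p <- cohort_params(n_subjects = 2, tasks_per_subject = 2,
                     task_duration_s = 120, fog_rate = 4,
                     modalities = "tibia_acc", seed = 21)
  co <- simulate_cohort(p)
  a <- co$annotations
  expect_true(all(a$start_s < a$end_s))
  expect_true(all(a$start_s >= 0 & a$end_s <= 120))
  for (key in unique(paste(a$subject_id, a$task_id))) {
    aa <- a[paste(a$subject_id, a$task_id) == key, ]
    expect_true(all(diff(aa$start_s) > 0))
    if (nrow(aa) > 1)
      expect_true(all(aa$start_s[-1] - aa$end_s[-nrow(aa)] >= 2))
  }
})

test_that("walking and freezing regimes concentrate power in their bands", {
  # long clean segments: >= 70% of 0.5-16 Hz power inside the regime band
  p <- cohort_params(n_subjects = 1, tasks_per_subject = 1,
                     task_duration_s = 60, fog_rate = 0,
                     modalities = "tibia_acc", seed = 33)
  s <- simulate_subject(p, 1)
  x <- s$recordings[[1]]$modalities$tibia_acc$samples[1, ]
  sp <- psd_estimate(x, fs = 100, seg_len_s = 4)
  walk_frac <- band_power(sp, 0.5, 3) / band_power(sp, 0.5, 16)
  expect_gte(walk_frac, 0.7)
  # a forced all-FOG segment via a single long episode
  p2 <- p
  s2 <- with(p2, NULL)
  ann <- data.frame(subject_id = "S01", task_id = "T01",
                    start_s = 0, end_s = 60)
  t <- seq(0, 60 - 1 / 100, by = 1 / 100)
  set.seed(1)
  fog_sig <- fogmm:::inertial_channel(t, rep(TRUE, length(t)), 1.8, 5.5,
                                      0.5, 0.1)
  sp2 <- psd_estimate(fog_sig, fs = 100, seg_len_s = 4)
  fog_frac <- band_power(sp2, 3, 8) / band_power(sp2, 0.5, 16)
  expect_gte(fog_frac, 0.7)
})

test_that("freeze-band power fraction rises inside episodes", {
  # direct periodogram integration per episode across several subjects
  p <- cohort_params(n_subjects = 4, tasks_per_subject = 2,
                     task_duration_s = 120, fog_rate = 2,
                     fog_amplitude_ratio = 0.5, noise_sd = c(inertial = 0.05),
                     modalities = "tibia_acc", seed = 13)
  co <- simulate_cohort(p)
  ann <- co$annotations
  ann <- ann[ann$end_s - ann$start_s >= 4, ]
  ratio_in_band <- function(x, fs) {
    sp <- psd_estimate(x, fs, seg_len_s = 2)
    band_power(sp, 3, 8) / band_power(sp, 0.5, 16)
  }
  better <- logical(0)
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    rec <- Filter(function(r) r$subject_id == a$subject_id &&
                    r$task_id == a$task_id, co$recordings)[[1]]
    x <- rec$modalities$tibia_acc$samples[1, ]
    fs <- rec$modalities$tibia_acc$fs
    inside <- x[(round(a$start_s * fs) + 1):round(a$end_s * fs)]
    out_ix <- setdiff(seq_along(x),
                      (round(a$start_s * fs) + 1):round(a$end_s * fs))
    # contiguous leading walking stretch as the outside reference
    lead <- out_ix[out_ix < round(a$start_s * fs)]
    if (length(lead) < 400) next
    outside <- x[tail(lead, 2000)]
    better <- c(better, ratio_in_band(inside, fs) > ratio_in_band(outside, fs))
  }
  expect_gt(length(better), 20)
  expect_gte(mean(better), 0.95)
})

test_that("SC tonic drift dominates and phasic bumps precede episodes", {
  s <- small_multimodal()
  rec <- s$processed
  sc <- rec$modalities$sc
  tonic <- sc$samples[match("tonic", sc$channel_names), ]
  detrended <- tonic - (fitted <- {
    t <- seq_along(tonic)
    cf <- coef(lm(tonic ~ t))
    cf[1] + cf[2] * t
  })
  expect_lt(var(detrended), 0.25 * var(tonic))
})

test_that("cohort round-trips through the CSV/JSON disk layout", {
  p <- cohort_params(n_subjects = 1, tasks_per_subject = 1,
                     task_duration_s = 60, fog_rate = 4,
                     modalities = c("tibia_acc", "sc"), seed = 17)
  co <- simulate_cohort(p)
  expect_gt(nrow(co$annotations), 0)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(back$annotations$start_s, co$annotations$start_s,
               tolerance = 1e-12)
  r0 <- co$recordings[[1]]; r1 <- back$recordings[[1]]
  expect_equal(unname(r1$modalities$tibia_acc$samples),
               unname(r0$modalities$tibia_acc$samples), tolerance = 1e-12)
  expect_equal(r1$modalities$tibia_acc$fs, 100)
})
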