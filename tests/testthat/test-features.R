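# Spectral estimation, band powers, freeze indices, time features, the
# per-sensor column contracts and range normalization.

test_that("Welch PSD locates tones and satisfies Parseval", {
  x <- sine(5, 500, 3)
  sp <- psd_estimate(x)
  expect_lte(abs(sp$freq[which.max(sp$power)] - 5), 1)
  expect_true(all(sp$power >= 0))
  # Parseval over white-noise draws
  errs <- vapply(1:20, function(i) {
    z <- with_seed_test(100 + i, rnorm(2500, sd = 2))
    sp <- psd_estimate(z)
    df <- sp$freq[2] - sp$freq[1]
    abs(sum(sp$power) * df - mean((z - mean(z))^2)) / mean((z - mean(z))^2)
  }, 0)
  expect_lt(mean(errs), 0.10)
  expect_error(psd_estimate(rnorm(100)), "too short")
})

test_that("equal-amplitude tones have equal band power within 5%", {
  # 3 s segments resolve the 1 Hz tone fully above the 0.5 Hz band edge
  x <- sine(1, 500, 12) + sine(5, 500, 12)
  sp <- psd_estimate(x, seg_len_s = 3)
  p1 <- band_power(sp, 0.5, 3); p5 <- band_power(sp, 3, 8)
  expect_lt(abs(p1 - p5) / max(p1, p5), 0.05)
  expect_error(band_power(sp, 8, 3), "invalid band")
})

test_that("freeze index and freeze ratio behave as band-power ratios", {
  sp1 <- psd_estimate(sine(1, 500, 12))
  sp5 <- psd_estimate(sine(5, 500, 12))
  spb <- psd_estimate(sine(1, 500, 12) + sine(5, 500, 12), seg_len_s = 3)
  expect_lt(freeze_index(sp1), 0.05)      # pure locomotion tone
  expect_gt(freeze_index(sp5), 20)        # pure freeze tone
  expect_gt(freeze_ratio(sp5), 0.95)
  expect_equal(freeze_index(spb), 1, tolerance = 0.05)
  expect_equal(freeze_ratio(spb), 0.5, tolerance = 0.03)
  # zero locomotion power -> Inf sentinel
  zero_spec <- structure(list(freq = 0:30, power = c(rep(0, 10), 1, rep(0, 20)),
                              fs = 60), class = "fog_psd")
  expect_equal(freeze_index(zero_spec), Inf)
})

test_that("spectral moments: tones, flat spectra, weighted means", {
  sp <- psd_estimate(sine(5, 500, 3))
  m <- spectral_moments(sp)
  expect_lte(abs(m[["dominant_freq"]] - 5), 1)
  expect_lte(abs(m[["mean_freq"]] - 5), 1)
  expect_lte(abs(m[["median_freq"]] - 5), 1)
  expect_lt(m[["spec_entropy"]], 0.25)    # concentrated spectrum
  # two equal tones at 2 and 6 Hz: power-weighted mean ~ 4 Hz
  m2 <- spectral_moments(psd_estimate(sine(2, 500, 10) + sine(6, 500, 10)))
  expect_equal(m2[["mean_freq"]], 4, tolerance = 0.25)
  # white noise: entropy approaches 1
  ent <- vapply(1:10, function(i)
    spectral_moments(psd_estimate(with_seed_test(i, rnorm(5000))))[["spec_entropy"]],
    0)
  expect_gt(mean(ent), 0.9)
  expect_error(spectral_moments(structure(list(freq = 0:10, power = rep(0, 11)),
                                          class = "fog_psd")), "all-zero")
})

test_that("time features match closed forms on a unit sine", {
  x <- sine(1, 500, 3)
  f <- time_features(x, 500)
  expect_equal(f[["n_zero_cross"]], 6)
  expect_equal(f[["n_peaks"]], 3)
  expect_equal(f[["rms"]], sqrt(0.5), tolerance = 1e-3)
  expect_equal(f[["zero_cross_rate"]], 2, tolerance = 1e-9)
  expect_equal(f[["max_amp"]], 1, tolerance = 1e-4)
  expect_equal(f[["range"]], 2, tolerance = 1e-4)
  expect_equal(f[["mean_peak_height"]], 1, tolerance = 1e-4)
  expect_equal(f[["mean_peak_dist"]], 1, tolerance = 1e-2)
  z <- time_features(rep(0, 1500), 500)
  expect_equal(z[["rms"]], 0)
  expect_equal(z[["range"]], 0)
  expect_equal(z[["n_zero_cross"]], 0)
  expect_equal(z[["n_peaks"]], 0)
  expect_equal(z[["mean_peak_dist"]], 0)
})

test_that("per-sensor column totals match the published contract", {
  s <- small_multimodal()
  rec <- s$processed
  w <- segment_windows(rec, s$annotations)
  pick <- function(mod, j) {
    st <- round(w$start_s[j] * 500)
    rec$modalities[[mod]]$samples[, (st + 1):(st + 1500), drop = FALSE]
  }
  ft <- extract_tibia(pick("tibia_acc", 1), pick("tibia_gyro", 1))
  expect_length(ft, 186)
  expect_false(any(duplicated(names(ft))))
  fw <- extract_wrist(pick("wrist_acc", 1), pick("wrist_gyro", 1))
  expect_length(fw, 168)
  expect_false(any(duplicated(names(fw))))
  eegw <- pick("eeg", 1)
  rownames(eegw) <- rec$modalities$eeg$channel_names
  fe <- extract_eeg(eegw)
  expect_length(fe, 1107)
  expect_false(any(duplicated(names(fe))))
  expect_equal(sum(grepl("^eeg\\.msc\\.", names(fe))), 153 * 5)
  scs <- pick("sc", 1)
  d1 <- fogmm:::central_diff(scs[2, ], 500)
  fsc <- extract_sc(scs[2, ], d1, fogmm:::central_diff(d1, 500), scs[3, ])
  expect_length(fsc, 39)
  expect_error(extract_eeg(eegw[-1, ]), "18 bipolar")
  expect_error(extract_tibia(pick("tibia_acc", 1)[-1, , drop = FALSE],
                             pick("tibia_gyro", 1)), "3 accelerometer")
})

test_that("driver rows equal the single-window extractors", {
  s <- small_multimodal()
  rec <- s$processed
  w <- segment_windows(rec, s$annotations)
  f <- extract_features(rec, w, sensors = "tibia")
  j <- 5
  st <- round(w$start_s[j] * 500)
  acc <- rec$modalities$tibia_acc$samples[, (st + 1):(st + 1500)]
  gyr <- rec$modalities$tibia_gyro$samples[, (st + 1):(st + 1500)]
  expect_equal(f$x[j, ], extract_tibia(acc, gyr), tolerance = 1e-12)
})

test_that("MSC is 1 for identical channels and small under independence", {
  fs <- 500
  base <- with_seed_test(5, rnorm(1500))
  X <- rbind(matrix(rep(base, 2), 2, byrow = TRUE),
             matrix(with_seed_test(6, rnorm(16 * 1500)), 16))
  rownames(X) <- paste0("ch", 1:18)
  fe <- extract_eeg(X, fs)
  msc_dup <- fe[grepl("^eeg\\.msc\\.ch1\\|ch2\\.", names(fe))]
  expect_true(all(msc_dup > 0.999))
  # independent white noise channels: band MSC stays small on 3 s windows
  msc_ind <- fe[grepl("^eeg\\.msc\\.ch1[0-7]\\|", names(fe))]
  expect_lt(mean(msc_ind), 0.3)
})

test_that("EEG band-shifted oscillations raise theta power during freezing", {
  p <- cohort_params(n_subjects = 1, tasks_per_subject = 1,
                     task_duration_s = 40, fog_rate = 3,
                     modalities = "eeg", seed = 19)
  s <- simulate_subject(p, 1)
  ann <- s$annotations[s$annotations$end_s - s$annotations$start_s >= 4, ]
  skip_if(nrow(ann) == 0, "no long episode in this draw")
  rec <- preprocess_recording(s$recordings[[1]])
  # F3-C3 carries the C3 theta oscillator (F3 is not a theta site)
  ch <- match("F3-C3", rec$modalities$eeg$channel_names)
  x <- rec$modalities$eeg$samples[ch, ]
  a <- ann[1, ]
  inside <- x[(round(a$start_s * 500) + 1):round(a$end_s * 500)]
  outside_ix <- setdiff(seq_along(x), (round(a$start_s * 500) + 1):round(a$end_s * 500))
  outside <- x[outside_ix[seq_len(min(10000, length(outside_ix)))]]
  th_in <- band_power(psd_estimate(inside, 500), 4, 8)
  th_out <- band_power(psd_estimate(outside, 500), 4, 8)
  expect_gt(th_in, th_out)
})

test_that("range normalization maps to [0,1], clips held-out rows, idempotent", {
  x <- cbind(a = c(2, 4, 6), b = c(1, 0, 3))
  n <- range_normalize(x)
  expect_equal(unname(n$x[, "a"]), c(0, 0.5, 1))
  expect_true(all(n$x >= 0 & n$x <= 1))
  # held-out transform with training stats + clipping
  held <- range_normalize(cbind(a = c(8, 1), b = c(2, -5)), n$ranges)
  expect_equal(unname(held$x[, "a"]), c(1, 0))
  # idempotence
  again <- range_normalize(n$x)
  expect_equal(again$x, n$x)
  # constant columns dropped with warning
  expect_warning(cd <- range_normalize(cbind(a = 1:3, b = rep(2, 3))),
                 "constant")
  expect_equal(colnames(cd$x), "a")
  # non-finite sentinels clip to the bounds
  tr <- range_normalize(cbind(a = c(2, 4, 6)))
  inf <- range_normalize(cbind(a = c(3, Inf)), tr$ranges)
  expect_equal(unname(inf$x[, "a"]), c(0.25, 1))
})

test_that("feature directions separate regimes on synthetic windows", {
  d <- small_cohort_fit_data()
  y <- as.numeric(d$windows$label == "FOG")
  fr <- d$x[, "tibia_acc.x.freeze_ratio"]
  lb <- d$x[, "tibia_acc.x.loc_band_power"]
  expect_gt(cor(fr, y), 0)
  expect_lt(cor(lb, y), 0)
  expect_gt(nrow(d$x), 200)
})

test_that("feature dictionary records provenance for every column", {
  d <- small_cohort_fit_data()
  dict <- feature_dictionary(colnames(d$x))
  expect_equal(nrow(dict), ncol(d$x))
  expect_setequal(unique(dict$sensor), c("tibia_acc", "tibia_gyro"))
  expect_setequal(unique(dict$domain), c("time", "frequency"))
  expect_equal(sum(dict$domain == "time"), 14 * 6)
})
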