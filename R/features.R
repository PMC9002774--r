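# Window-level feature batteries. Column totals per sensor are a hard
# contract: tibial inertial 186, wrist inertial 168, EEG 1107, SC 39. The
# full registry is exported via feature_dictionary().

eeg_bands <- list(delta = c(1.6, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta1 = c(13, 20), beta2 = c(20, 30))

# ---- scalar helpers --------------------------------------------------------

rms <- function(x) sqrt(mean(x^2))

# Zero crossings counted as changes of sign(x) (a touched exact zero counts);
# constant signals give 0.
n_zero_crossings <- function(x) sum(diff(sign(x)) != 0)

# Local maxima with prominence >= min_prom. Prominence of a peak is its
# height above the higher of the two deepest valleys separating it from
# higher terrain (or the signal edge).
find_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]; h <- x[i]
    j <- i - 1L; lmin <- h
    while (j >= 1L && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    j <- i + 1L; rmin <- h
    while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
    keep[k] <- (h - max(lmin, rmin)) >= min_prom
  }
  cand[keep]
}

n_local_max <- function(x) sum(diff(sign(diff(x))) < 0)
n_local_min <- function(x) sum(diff(sign(diff(x))) > 0)

ls_slope <- function(x, fs) {
  t <- (seq_along(x) - 1) / fs
  tc <- t - mean(t)
  sum(tc * (x - mean(x))) / sum(tc^2)
}

# ---- per-channel time-domain battery (13 features) -------------------------

time_features_core <- function(x, fs) {
  zc <- n_zero_crossings(x)
  dur <- length(x) / fs
  pk <- find_peaks(x, min_prom = 0.1 * sd_pop(x))
  c(rms = rms(x), mean = mean(x), std = sd_pop(x),
    n_zero_cross = zc, zero_cross_rate = zc / dur,
    n_peaks = length(pk),
    mean_peak_dist = if (length(pk) > 1) mean(diff(pk)) / fs else 0,
    mean_peak_height = if (length(pk) > 0) mean(x[pk]) else 0,
    energy = sum(x^2) / fs,
    max_amp = max(x), min_amp = min(x), range = max(x) - min(x),
    integral = sum(x) / fs)
}

#' Time-domain features of a single analysis window
#'
#' RMS, mean, standard deviation, zero-crossing count and rate, peak count /
#' mean inter-peak distance / mean peak height (local maxima with prominence
#' at least 0.1 of the window standard deviation), energy, extreme amplitudes,
#' range and integral. Windows with no detected peaks report 0 for the
#' peak-derived features.
#'
#' @param x Numeric vector (one window of one channel).
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector of 13 features.
#' @export
time_features <- function(x, fs = 500) time_features_core(x, fs)

# ---- frequency-domain batteries --------------------------------------------

# shared spectral-moment block (vector of 11 named values)
psd_moment_block <- function(spec) {
  tot <- sum(spec$power)
  if (tot == 0)
    return(c(total_power = 0, mean_power = 0, max_power = 0, std_power = 0,
             dominant_freq = 0, mean_freq = 0, median_freq = 0,
             psd_skewness = 0, psd_kurtosis = 0, spec_energy = 0,
             spec_entropy = 0))
  spectral_moments(spec)
}

# 17-feature battery used per tibial axis
freq_features_full <- function(spec) {
  m <- psd_moment_block(spec)
  loco <- band_power(spec, 0.5, 3); frz <- band_power(spec, 3, 8)
  in_loco <- spec$freq >= 0.5 & spec$freq <= 3
  in_frz <- spec$freq >= 3 & spec$freq <= 8
  c(m[c("total_power", "mean_power", "max_power", "std_power")],
    loc_band_power = loco, freeze_band_power = frz,
    loc_band_power_std = sd_pop(spec$power[in_loco]),
    freeze_band_power_std = sd_pop(spec$power[in_frz]),
    freeze_index = if (loco == 0) Inf else frz / loco,
    freeze_ratio = if (loco + frz == 0) 0 else frz / (loco + frz),
    m[c("psd_skewness", "psd_kurtosis", "spec_energy", "spec_entropy",
        "dominant_freq", "mean_freq", "median_freq")])
}

# 7-feature battery used per wrist component
freq_features_basic <- function(spec) {
  m <- psd_moment_block(spec)
  m[c("total_power", "mean_power", "std_power", "max_power",
      "dominant_freq", "mean_freq", "median_freq")]
}

# 16-feature EEG battery (per bipolar channel)
freq_features_eeg <- function(spec) {
  m <- psd_moment_block(spec)
  bands <- vapply(eeg_bands, function(b) band_power(spec, b[1], b[2]), 0)
  names(bands) <- paste0(names(eeg_bands), "_power")
  c(m[c("total_power", "mean_power", "max_power", "std_power",
        "psd_skewness", "psd_kurtosis", "spec_energy", "spec_entropy",
        "dominant_freq", "median_freq", "mean_freq")], bands)
}

# wrist magnitude frequency batteries
freq_features_wrist_mag <- function(spec, one_hz_bands) {
  base <- freq_features_basic(spec)
  extra <- c(loc_band_power = band_power(spec, 0.5, 3),
             freeze_band_power = band_power(spec, 3, 8))
  if (one_hz_bands) {
    bp <- vapply(0:15, function(lo) band_power(spec, lo, lo + 1), 0)
    names(bp) <- sprintf("power_%d_%d", 0:15, 1:16)
    extra <- c(extra, bp,
               power_9_12 = band_power(spec, 9, 12),
               power_13_16 = band_power(spec, 13, 16))
  }
  c(base, extra)
}

# ---- per-sensor window extractors ------------------------------------------

axis_pairs <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L))  # x:xy, y:yz, z:xz

pearson_or_zero <- function(a, b) {
  sa <- sd_pop(a); sb <- sd_pop(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Tibial inertial feature battery for one window (186 features)
#'
#' 17 frequency- plus 14 time-domain features per axis (the 14th is the
#' Pearson correlation with the companion axis: x with y, y with z, z with x)
#' for the 3 axes of the accelerometer and of the gyroscope.
#'
#' @param acc,gyro Numeric 3 x n matrices (axes x, y, z).
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector of exactly 186 features.
#' @export
extract_tibia <- function(acc, gyro, fs = 500) {
  if (nrow(acc) != 3 || nrow(gyro) != 3)
    stop("tibial extraction needs 3 accelerometer and 3 gyroscope channels",
         call. = FALSE)
  out <- c()
  for (sensor in c("tibia_acc", "tibia_gyro")) {
    X <- if (sensor == "tibia_acc") acc else gyro
    for (ax in 1:3) {
      spec <- psd_estimate(X[ax, ], fs)
      v <- c(freq_features_full(spec), time_features_core(X[ax, ], fs),
             axes_corr = pearson_or_zero(X[axis_pairs[ax, 1], ],
                                         X[axis_pairs[ax, 2], ]))
      names(v) <- paste(sensor, c("x", "y", "z")[ax], names(v), sep = ".")
      out <- c(out, v)
    }
  }
  out
}

#' Wrist inertial feature battery for one window (168 features)
#'
#' Features are computed on the Euclidean signal magnitude and on each of the
#' three components of the accelerometer and gyroscope. Per component: 7
#' frequency + 13 time features. Accelerometer magnitude: 27 frequency
#' (including sixteen 1 Hz band powers, the locomotion and freeze band powers
#' and the 9--12 / 13--16 Hz powers), 3 time features and the 3 pairwise axis
#' correlations. Gyroscope magnitude: 9 frequency, 3 time, 3 correlations.
#'
#' @inheritParams extract_tibia
#' @return Named numeric vector of exactly 168 features.
#' @export
extract_wrist <- function(acc, gyro, fs = 500) {
  if (nrow(acc) != 3 || nrow(gyro) != 3)
    stop("wrist extraction needs 3 accelerometer and 3 gyroscope channels",
         call. = FALSE)
  out <- c()
  for (sensor in c("wrist_acc", "wrist_gyro")) {
    X <- if (sensor == "wrist_acc") acc else gyro
    mag <- sqrt(colSums(X^2))
    spec_m <- psd_estimate(mag, fs)
    vm <- c(freq_features_wrist_mag(spec_m, one_hz_bands = sensor == "wrist_acc"),
            rms = rms(mag), mean = mean(mag), std = sd_pop(mag),
            corr_xy = pearson_or_zero(X[1, ], X[2, ]),
            corr_xz = pearson_or_zero(X[1, ], X[3, ]),
            corr_yz = pearson_or_zero(X[2, ], X[3, ]))
    names(vm) <- paste(sensor, "mag", names(vm), sep = ".")
    out <- c(out, vm)
    for (ax in 1:3) {
      spec <- psd_estimate(X[ax, ], fs)
      v <- c(freq_features_basic(spec), time_features_core(X[ax, ], fs))
      names(v) <- paste(sensor, c("x", "y", "z")[ax], names(v), sep = ".")
      out <- c(out, v)
    }
  }
  out
}

#' EEG feature battery for one window (1107 features)
#'
#' Per bipolar channel: 16 frequency features (spectral moments, shape
#' descriptors and the five band powers delta 1.6--4, theta 4--8, alpha
#' 8--13, beta1 13--20, beta2 20--30 Hz) and 3 time features; plus the
#' magnitude squared coherence averaged within each of the 5 bands for all
#' 153 channel pairs.
#'
#' @param eeg Numeric 18 x n matrix of bipolar derivations (rownames used as
#'   channel names).
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector of exactly 1107 features.
#' @export
extract_eeg <- function(eeg, fs = 500) {
  if (nrow(eeg) != 18)
    stop("EEG extraction needs the 18 bipolar derivations", call. = FALSE)
  ch_names <- rownames(eeg) %||% paste0("ch", 1:18)
  seg_len <- min(as.integer(fs), ncol(eeg))
  out <- c()
  X_list <- vector("list", 18)
  for (i in 1:18) {
    x <- eeg[i, ]
    spec <- psd_estimate(x, fs)
    v <- c(freq_features_eeg(spec), rms = rms(x), mean = mean(x),
           std = sd_pop(x))
    names(v) <- paste("eeg", ch_names[i], names(v), sep = ".")
    out <- c(out, v)
    X_list[[i]] <- welch_fft(x, seg_len)
  }
  msc <- msc_band_matrix(X_list, fs, seg_len, eeg_bands)
  mv <- as.vector(t(msc$msc))
  pair_names <- apply(msc$pairs, 2, function(pp)
    paste(ch_names[pp[1]], ch_names[pp[2]], sep = "|"))
  names(mv) <- paste("eeg.msc", rep(pair_names, each = length(eeg_bands)),
                     rep(names(eeg_bands), length(pair_names)), sep = ".")
  c(out, mv)
}

#' Skin-conductance feature battery for one window (39 features)
#'
#' Phasic component: 10 frequency + 9 time features; first and second
#' derivatives of the phasic component: 8 time features each; tonic
#' component: 3 frequency features plus the least-squares slope.
#'
#' @param phasic,der1,der2,tonic Numeric vectors (one window each).
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector of exactly 39 features.
#' @export
extract_sc <- function(phasic, der1, der2, tonic, fs = 500) {
  spec_p <- psd_estimate(phasic, fs)
  mp <- psd_moment_block(spec_p)
  vp <- c(mp[c("total_power", "mean_power", "std_power", "psd_skewness",
               "psd_kurtosis", "spec_energy", "spec_entropy",
               "dominant_freq", "median_freq", "mean_freq")],
          rms = rms(phasic), mean = mean(phasic), std = sd_pop(phasic),
          median = median(phasic), min = min(phasic), max = max(phasic),
          range = max(phasic) - min(phasic),
          n_local_min = n_local_min(phasic), n_local_max = n_local_max(phasic))
  names(vp) <- paste("sc.phasic", names(vp), sep = ".")
  der_block <- function(d, nm) {
    v <- c(mean = mean(d), median = median(d), std = sd_pop(d),
           min = min(d), max = max(d), range = max(d) - min(d),
           n_local_min = n_local_min(d), n_local_max = n_local_max(d))
    names(v) <- paste("sc", nm, names(v), sep = ".")
    v
  }
  spec_t <- psd_estimate(tonic, fs)
  mt <- psd_moment_block(spec_t)
  vt <- c(mt[c("total_power", "mean_freq", "median_freq")],
          slope = ls_slope(tonic, fs))
  names(vt) <- paste("sc.tonic", names(vt), sep = ".")
  c(vp, der_block(der1, "der1"), der_block(der2, "der2"), vt)
}

# ---- cohort-level driver ---------------------------------------------------

window_matrix <- function(x, starts, win) {
  idx <- outer(seq_len(win), starts, "+")
  matrix(x[idx], nrow = win)
}

#' Extract the feature matrix for a windowed recording
#'
#' Runs the per-sensor batteries of \code{\link{extract_tibia}},
#' \code{\link{extract_wrist}}, \code{\link{extract_eeg}} and
#' \code{\link{extract_sc}} over every window of a processed recording.
#' Derivatives of the phasic skin-conductance component are central
#' differences computed on the full-length signal before windowing.
#'
#' @param recording A processed \code{fog_recording} (500 Hz).
#' @param windows A \code{fog_windows} for the same recording.
#' @param sensors Which sensor groups to extract (subset of
#'   \code{c("tibia", "wrist", "eeg", "sc")}).
#' @return Object of class \code{fog_features}: list with \code{x} (windows x
#'   features matrix), \code{windows} and \code{dictionary}.
#' @export
extract_features <- function(recording, windows,
                             sensors = c("tibia", "wrist", "eeg", "sc")) {
  sensors <- match.arg(sensors, several.ok = TRUE)
  fs <- attr(windows, "fs")
  win <- as.integer(round(attr(windows, "window_len_s") * fs))
  starts <- as.integer(round(windows$start_s * fs))
  n_win <- nrow(windows)
  get_wm <- function(mod, ch) {
    window_matrix(recording$modalities[[mod]]$samples[ch, ], starts, win)
  }
  blocks <- list()
  if ("tibia" %in% sensors) {
    Wa <- lapply(1:3, function(ch) get_wm("tibia_acc", ch))
    Wg <- lapply(1:3, function(ch) get_wm("tibia_gyro", ch))
    blocks$tibia <- t(vapply(seq_len(n_win), function(j)
      extract_tibia(rbind(Wa[[1]][, j], Wa[[2]][, j], Wa[[3]][, j]),
                    rbind(Wg[[1]][, j], Wg[[2]][, j], Wg[[3]][, j]), fs),
      numeric(186)))
  }
  if ("wrist" %in% sensors) {
    Wa <- lapply(1:3, function(ch) get_wm("wrist_acc", ch))
    Wg <- lapply(1:3, function(ch) get_wm("wrist_gyro", ch))
    blocks$wrist <- t(vapply(seq_len(n_win), function(j)
      extract_wrist(rbind(Wa[[1]][, j], Wa[[2]][, j], Wa[[3]][, j]),
                    rbind(Wg[[1]][, j], Wg[[2]][, j], Wg[[3]][, j]), fs),
      numeric(168)))
  }
  if ("eeg" %in% sensors) {
    m <- recording$modalities$eeg
    We <- lapply(1:18, function(ch) get_wm("eeg", ch))
    blocks$eeg <- t(vapply(seq_len(n_win), function(j) {
      w <- do.call(rbind, lapply(We, function(W) W[, j]))
      rownames(w) <- m$channel_names
      extract_eeg(w, fs)
    }, numeric(1107)))
  }
  if ("sc" %in% sensors) {
    m <- recording$modalities$sc
    phasic <- m$samples[match("phasic", m$channel_names), ]
    tonic <- m$samples[match("tonic", m$channel_names), ]
    d1 <- central_diff(phasic, fs)
    d2 <- central_diff(d1, fs)
    Wp <- window_matrix(phasic, starts, win)
    W1 <- window_matrix(d1, starts, win)
    W2 <- window_matrix(d2, starts, win)
    Wt <- window_matrix(tonic, starts, win)
    blocks$sc <- t(vapply(seq_len(n_win), function(j)
      extract_sc(Wp[, j], W1[, j], W2[, j], Wt[, j], fs), numeric(39)))
  }
  x <- do.call(cbind, blocks)
  structure(list(x = x, windows = windows, dictionary = feature_dictionary(colnames(x))),
            class = "fog_features")
}

central_diff <- function(x, fs) {
  n <- length(x)
  d <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * fs
  d
}

#' Machine-readable registry of feature columns
#'
#' Parses feature names of the form \code{sensor.channel.feature} into a
#' provenance table (sensor, channel or channel pair, time/frequency domain,
#' band where applicable) so the enumeration behind the per-sensor column
#' totals is auditable.
#'
#' @param feature_names Character vector of feature column names.
#' @return Data frame with columns \code{name, sensor, channel, domain,
#'   band}.
#' @export
feature_dictionary <- function(feature_names) {
  time_feats <- c("rms", "mean", "std", "n_zero_cross", "zero_cross_rate",
                  "n_peaks", "mean_peak_dist", "mean_peak_height", "energy",
                  "max_amp", "min_amp", "range", "integral", "axes_corr",
                  "corr_xy", "corr_xz", "corr_yz", "median", "min", "max",
                  "n_local_min", "n_local_max", "slope")
  parse1 <- function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[2] == "msc") {
      data.frame(name = nm, sensor = "eeg", channel = parts[3],
                 domain = "frequency", band = parts[4])
    } else {
      sensor <- if (parts[1] == "sc") "sc" else parts[1]
      channel <- parts[2]
      feat <- paste(parts[-(1:2)], collapse = ".")
      band <- NA_character_
      for (b in names(eeg_bands))
        if (startsWith(feat, b)) band <- b
      if (grepl("loc_band|power_", feat)) band <- "locomotion/other"
      if (grepl("freeze", feat)) band <- "freeze"
      data.frame(name = nm, sensor = sensor, channel = channel,
                 domain = if (feat %in% time_feats) "time" else "frequency",
                 band = band)
    }
  }
  out <- do.call(rbind, lapply(feature_names, parse1))
  rownames(out) <- NULL
  out
}

#' Range-normalize feature columns onto [0, 1]
#'
#' Min--max normalization. The per-column minima and maxima are computed on
#' the fitting rows only (training data); when applied to held-out rows the
#' transformed values are clipped to [0, 1], so no information from test rows
#' leaks into the scaling. Non-finite sentinel values map to the nearest
#' bound. Constant columns (on the fitting rows) are dropped with a warning.
#'
#' @param x Numeric matrix (windows x features).
#' @param ranges Optional list with \code{min} and \code{max} named vectors
#'   from a previous fit; if \code{NULL} they are computed from \code{x}.
#' @return List with \code{x} (normalized matrix) and \code{ranges}.
#' @export
range_normalize <- function(x, ranges = NULL) {
  if (is.null(ranges)) {
    fin <- apply(x, 2, function(col) {
      f <- col[is.finite(col)]
      if (length(f) == 0) c(0, 0) else range(f)
    })
    ranges <- list(min = fin[1, ], max = fin[2, ])
    keep <- ranges$max > ranges$min
    if (any(!keep)) {
      warning(sprintf("dropping %d constant feature column(s)", sum(!keep)))
      x <- x[, keep, drop = FALSE]
      ranges$min <- ranges$min[keep]; ranges$max <- ranges$max[keep]
    }
  } else {
    x <- x[, names(ranges$min), drop = FALSE]
  }
  out <- sweep(x, 2, ranges$min, "-")
  out <- sweep(out, 2, ranges$max - ranges$min, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out[is.nan(out)] <- 0
  list(x = out, ranges = ranges)
}
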