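#' Z-score standardization of a signal
#'
#' Rescales a signal to zero mean and unit standard deviation, removing
#' inter-subject amplitude differences before feature extraction. The
#' population (1/n) standard deviation is used.
#'
#' @param signal Numeric vector of at least two finite samples.
#' @return Numeric vector of the same length with mean 0 and (population)
#'   standard deviation 1.
#' @examples
#' zscore_standardize(c(2, 4, 6))
#' @export
zscore_standardize <- function(signal) {
  if (length(signal) < 2) stop("signal must have at least 2 samples", call. = FALSE)
  stopifnot_finite(signal)
  m <- mean(signal)
  s <- sqrt(mean((signal - m)^2))
  if (s == 0) stop("degenerate signal: zero standard deviation", call. = FALSE)
  (signal - m) / s
}

#' Resample a signal to the common 500 Hz analysis rate
#'
#' Band-limited polyphase resampling to 500 Hz. All modalities are brought to
#' this common rate before windowing so window boundaries align across sensors.
#'
#' @param signal Numeric vector.
#' @param fs_in Input sampling rate in Hz (positive).
#' @param fs_out Output rate, 500 Hz by default.
#' @return Numeric vector sampled at \code{fs_out}; duration preserved within
#'   one input sample period.
#' @export
resample_to_500hz <- function(signal, fs_in, fs_out = 500) {
  if (!is.numeric(fs_in) || length(fs_in) != 1 || !is.finite(fs_in) || fs_in <= 0)
    stop("fs_in must be a positive number", call. = FALSE)
  if (fs_in == fs_out) return(as.numeric(signal))
  # express the ratio as a small rational p/q
  r <- fs_out / fs_in
  q <- 1L
  while (abs(r * q - round(r * q)) > 1e-9 && q < 10000L) q <- q + 1L
  p <- as.integer(round(r * q))
  as.numeric(signal::resample(as.numeric(signal), p, q))
}

# Zero-phase filtering with odd-reflection edge padding (the padding absorbs
# the filter start-up transient; the reflection preserves signal level and
# slope at the boundaries).
filtfilt_pad <- function(filt, x, padlen) {
  n <- length(x)
  p <- min(n - 1L, as.integer(padlen))
  if (p < 1) return(signal::filtfilt(filt, x))
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(p + 1):(p + n)]
}

# Forward-backward (zero-phase) filtering of a Butterworth/Chebyshev cascade.
# Each stage doubles its attenuation; no group delay is introduced, so window
# labels stay aligned with the annotations.
filt_cascade <- function(filters, x, padlen = 3 * length(x) %/% 10) {
  for (f in filters) x <- filtfilt_pad(f, x, padlen)
  x
}

#' Band-pass filter an inertial signal (0.5--16 Hz)
#'
#' Cascade of a 4th-order Butterworth high-pass at 0.5 Hz and a 5th-order
#' Butterworth low-pass at 16 Hz, applied zero-phase. The pass band covers the
#' locomotion band (0.5--3 Hz) and the freeze band (3--8 Hz).
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz (>= 100).
#' @return Filtered vector of the same length.
#' @export
filter_inertial <- function(signal, fs) {
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  if (16 >= fs / 2) stop("low-pass cutoff must be below Nyquist", call. = FALSE)
  hp <- signal::butter(4, 0.5 / (fs / 2), type = "high")
  lp <- signal::butter(5, 16 / (fs / 2), type = "low")
  filt_cascade(list(hp, lp), signal, padlen = 10 * fs)
}

#' Band-pass filter an EEG channel (1.6--30 Hz)
#'
#' Cascade of a 5th-order Chebyshev type-I high-pass at 1.6 Hz and a 6th-order
#' Chebyshev type-I low-pass at 30 Hz, zero-phase. The passband ripple is
#' 0.25 dB per pass; because each filter is applied forward and backward the
#' effective ripple is ~0.5 dB.
#'
#' @inheritParams filter_inertial
#' @param ripple_db Passband ripple per pass, in dB.
#' @return Filtered vector of the same length.
#' @export
filter_eeg <- function(signal, fs, ripple_db = 0.25) {
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  if (30 >= fs / 2) stop("low-pass cutoff must be below Nyquist", call. = FALSE)
  hp <- signal::cheby1(5, ripple_db, 1.6 / (fs / 2), type = "high")
  lp <- signal::cheby1(6, ripple_db, 30 / (fs / 2), type = "low")
  filt_cascade(list(hp, lp), signal, padlen = 2 * fs)
}

#' Default longitudinal bipolar EEG montage (18 derivations)
#'
#' Two temporal and two parasagittal anterior-to-posterior chains built from
#' the 26 scalp electrodes of the recording set. The exact derivation list is
#' a configurable input to \code{\link{make_bipolar_montage}}; this default is
#' the one used throughout the package and recorded in run manifests.
#'
#' @return Character matrix with 18 rows and columns \code{anterior},
#'   \code{posterior}.
#' @export
default_montage <- function() {
  pairs <- rbind(
    c("FP1", "F7"), c("F7", "FC5"), c("FC5", "CP5"), c("CP5", "P7"), c("P7", "O1"),
    c("FP2", "F8"), c("F8", "FC6"), c("FC6", "CP6"), c("CP6", "P8"), c("P8", "O2"),
    c("FP1", "F3"), c("F3", "C3"), c("C3", "P3"), c("P3", "O1"),
    c("FP2", "F4"), c("F4", "C4"), c("C4", "P4"), c("P4", "O2"))
  colnames(pairs) <- c("anterior", "posterior")
  pairs
}

#' Re-reference raw EEG electrodes to a longitudinal bipolar montage
#'
#' Each output channel is the difference between an anterior and a posterior
#' electrode, suppressing common-mode activity (references, line noise, broad
#' artifacts shared between neighbours).
#'
#' @param samples Numeric matrix, electrodes x time.
#' @param channel_names Character vector naming the rows of \code{samples}.
#' @param montage Two-column character matrix of electrode pairs
#'   (default \code{\link{default_montage}()}).
#' @return Numeric matrix, one row per derivation, rownames \code{"A-B"}.
#' @export
make_bipolar_montage <- function(samples, channel_names, montage = default_montage()) {
  missing <- setdiff(unique(as.vector(montage)), channel_names)
  if (length(missing) > 0)
    stop(sprintf("montage electrodes absent from recording: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  out <- samples[match(montage[, 1], channel_names), , drop = FALSE] -
    samples[match(montage[, 2], channel_names), , drop = FALSE]
  rownames(out) <- paste(montage[, 1], montage[, 2], sep = "-")
  out
}

#' Convert galvanic resistance to skin conductance
#'
#' @param resistance Numeric vector of positive resistance values (Mohm yields
#'   conductance in microsiemens).
#' @return Element-wise reciprocal.
#' @export
resistance_to_conductance <- function(resistance) {
  if (any(!is.finite(resistance)) || any(resistance <= 0))
    stop("resistance values must be positive and finite", call. = FALSE)
  1 / resistance
}

#' Decompose skin conductance into phasic and tonic components
#'
#' The conductance trace is low-pass filtered at 2 Hz (5th-order Butterworth,
#' zero-phase); rapid artifact transients are suppressed by replacing flagged
#' spans with a centered moving average; the phasic component (SCR) is
#' extracted with a 5th-order Butterworth high-pass at 0.5 Hz and the tonic
#' level (SCL) is the remainder, so that SCR + SCL reconstructs the filtered
#' conductance exactly.
#'
#' Transients are flagged where the absolute first difference exceeds 5 times
#' its median-absolute-deviation scale for runs shorter than 0.5 s; the
#' replacement moving-average window is \code{ma_window_s} (3--6 s sensible,
#' 4 s default).
#'
#' @param sc Conductance vector (microsiemens).
#' @param fs Sampling rate in Hz.
#' @param transient_mask Optional logical vector (same length) of spans to
#'   suppress, overriding automatic detection.
#' @param ma_window_s Moving-average window for transient replacement, seconds.
#' @return Object of class \code{fog_sc} with elements \code{sc_filtered},
#'   \code{scr}, \code{scl}, \code{fs}.
#' @export
sc_decompose <- function(sc, fs, transient_mask = NULL, ma_window_s = 4) {
  if (length(sc) == 0) stop("empty skin-conductance signal", call. = FALSE)
  stopifnot_finite(sc, "skin conductance")
  lp <- signal::butter(5, 2 / (fs / 2), type = "low")
  scf <- filtfilt_pad(lp, sc, 10 * fs)
  if (is.null(transient_mask)) transient_mask <- detect_sc_transients(sc, fs)
  if (any(transient_mask)) {
    ma <- centered_moving_average(scf, max(1L, as.integer(round(ma_window_s * fs))))
    scf[transient_mask] <- ma[transient_mask]
  }
  hp <- signal::butter(5, 0.5 / (fs / 2), type = "high")
  scr <- filtfilt_pad(hp, scf, 10 * fs)
  scl <- scf - scr
  structure(list(sc_filtered = scf, scr = scr, scl = scl, fs = fs),
            class = "fog_sc")
}

# Flag short spans whose first difference is an outlier (>5x the MAD scale of
# the differenced raw signal) lasting less than 0.5 s; flagged spans are
# dilated by 0.25 s on each side to cover the filter's spreading of the jump.
detect_sc_transients <- function(x, fs) {
  d <- c(0, abs(diff(x)))
  scale <- stats::mad(d)
  if (scale == 0) return(rep(FALSE, length(x)))
  flag <- d > 5 * scale
  r <- rle(flag)
  max_run <- as.integer(0.5 * fs)
  r$values <- r$values & r$lengths < max_run
  flag <- inverse.rle(r)
  if (!any(flag)) return(flag)
  k <- as.integer(0.25 * fs)
  ix <- which(flag)
  dil <- unique(pmin(pmax(rep(ix, each = 2 * k + 1) + (-k):k, 1L), length(x)))
  out <- rep(FALSE, length(x))
  out[dil] <- TRUE
  out
}

centered_moving_average <- function(x, w) {
  if (w %% 2 == 0) w <- w + 1L
  k <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - k)
  hi <- pmin(n, seq_len(n) + k)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Preprocess a raw multi-modal recording
#'
#' Applies the full per-modality conditioning chain and brings every channel
#' to 500 Hz: inertial and EEG channels are z-score standardized, band-pass
#' filtered at their native rate (0.5--16 Hz Butterworth for inertial,
#' 1.6--30 Hz Chebyshev for EEG after bipolar re-referencing) and resampled;
#' skin conductance is converted from resistance, resampled and decomposed
#' into phasic/tonic components (no z-scoring, preserving physical phasic and
#' tonic morphology).
#'
#' @param recording A \code{fog_recording} from \code{\link{simulate_subject}}
#'   or \code{\link{read_cohort}}.
#' @param montage Bipolar montage for EEG, see
#'   \code{\link{make_bipolar_montage}}.
#' @return A \code{fog_recording} with all modalities at 500 Hz; the EEG
#'   modality holds the 18 bipolar derivations and the \code{sc} modality
#'   holds channels \code{sc_filtered}, \code{phasic}, \code{tonic}.
#' @export
preprocess_recording <- function(recording, montage = default_montage()) {
  out <- recording
  for (mod in names(recording$modalities)) {
    m <- recording$modalities[[mod]]
    if (mod %in% c("tibia_acc", "tibia_gyro", "wrist_acc", "wrist_gyro")) {
      proc <- t(apply(m$samples, 1, function(ch)
        resample_to_500hz(filter_inertial(zscore_standardize(ch), m$fs), m$fs)))
      out$modalities[[mod]] <- list(channel_names = m$channel_names, fs = 500,
                                    samples = proc)
    } else if (mod == "eeg") {
      bip <- make_bipolar_montage(m$samples, m$channel_names, montage)
      proc <- t(apply(bip, 1, function(ch)
        resample_to_500hz(filter_eeg(zscore_standardize(ch), m$fs), m$fs)))
      out$modalities[[mod]] <- list(channel_names = rownames(bip), fs = 500,
                                    samples = proc)
    } else if (mod == "sc") {
      cond <- resistance_to_conductance(as.numeric(m$samples[1, ]))
      cond500 <- resample_to_500hz(cond, m$fs)
      comp <- sc_decompose(cond500, 500)
      out$modalities[[mod]] <- list(
        channel_names = c("sc_filtered", "phasic", "tonic"), fs = 500,
        samples = rbind(comp$sc_filtered, comp$scr, comp$scl))
    } else {
      stop(sprintf("unknown modality '%s'", mod), call. = FALSE)
    }
  }
  out$processed <- TRUE
  out
}
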