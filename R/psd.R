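# Welch spectral estimation and band-power primitives underlying all
# frequency-domain features (freeze index, band powers, spectral moments,
# magnitude-squared coherence).

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

# Segment start indices for Welch averaging: seg_len samples, 50% overlap,
# covering the window.
welch_offsets <- function(n, seg_len, overlap = 0.5) {
  hop <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  off <- seq.int(0L, n - seg_len, by = hop)
  off
}

# Complex segment FFT stack for one window (seg_len x n_segments), Hann
# tapered. Shared by auto- and cross-spectra.
welch_fft <- function(x, seg_len, overlap = 0.5) {
  off <- welch_offsets(length(x), seg_len, overlap)
  w <- hann_window(seg_len)
  segs <- vapply(off, function(o) x[(o + 1):(o + seg_len)] * w,
                 numeric(seg_len))
  mvfft(segs)
}

#' Welch power spectral density of one analysis window
#'
#' Averaged Hann-tapered periodogram over 1 s segments with 50% overlap,
#' giving a 1 Hz frequency resolution at the 500 Hz analysis rate. The
#' one-sided PSD integrates (approximately) to the signal variance.
#'
#' @param x Numeric vector, at least 256 samples.
#' @param fs Sampling rate, Hz.
#' @param seg_len_s Welch segment length, seconds.
#' @param overlap Fractional overlap between segments.
#' @return Object of class \code{fog_psd} with \code{freq} (Hz), \code{power}
#'   (one-sided PSD), and the estimator settings.
#' @export
psd_estimate <- function(x, fs = 500, seg_len_s = 1, overlap = 0.5) {
  if (length(x) < 256) stop("window too short for PSD estimation", call. = FALSE)
  seg_len <- as.integer(round(seg_len_s * fs))
  seg_len <- min(seg_len, length(x))
  X <- welch_fft(x, seg_len, overlap)
  w <- hann_window(seg_len)
  U <- sum(w^2)
  nf <- seg_len %/% 2 + 1
  P <- rowMeans(Mod(X[seq_len(nf), , drop = FALSE])^2) / (fs * U)
  scale <- rep(2, nf); scale[1] <- 1
  if (seg_len %% 2 == 0) scale[nf] <- 1
  P <- P * scale
  structure(list(freq = (seq_len(nf) - 1) * fs / seg_len, power = P,
                 fs = fs, seg_len = seg_len, overlap = overlap,
                 taper = "hann"),
            class = "fog_psd")
}

# Vectorized Welch PSD for a windows matrix (win_len x n_windows).
# Returns power matrix (n_freq x n_windows) plus the frequency grid.
welch_psd_matrix <- function(W, fs = 500, seg_len_s = 1, overlap = 0.5) {
  win_len <- nrow(W); n_win <- ncol(W)
  seg_len <- min(as.integer(round(seg_len_s * fs)), win_len)
  off <- welch_offsets(win_len, seg_len, overlap)
  n_seg <- length(off)
  w <- hann_window(seg_len)
  U <- sum(w^2)
  idx <- outer(seq_len(seg_len), off, "+")          # seg_len x n_seg
  # segment matrix with columns grouped by window: [win1 seg1..segk, win2 ...]
  S <- matrix(0, seg_len, n_seg * n_win)
  cols <- 0L
  for (j in seq_len(n_win)) {
    xs <- W[, j]
    for (k in seq_len(n_seg)) {
      cols <- cols + 1L
      S[, cols] <- xs[idx[, k]] * w
    }
  }
  X <- mvfft(S)
  nf <- seg_len %/% 2 + 1
  P2 <- Mod(X[seq_len(nf), , drop = FALSE])^2 / (fs * U)
  # average segments within each window
  arr <- array(P2, c(nf, n_seg, n_win))
  P <- colMeans(aperm(arr, c(2, 1, 3)))             # nf x n_win
  scale <- rep(2, nf); scale[1] <- 1
  if (seg_len %% 2 == 0) scale[nf] <- 1
  P <- P * scale
  list(freq = (seq_len(nf) - 1) * fs / seg_len, power = P)
}

#' Integrated band power of a spectral estimate
#'
#' Trapezoidal integral of the PSD over \code{[lo, hi]} Hz, with linear
#' interpolation at the band edges.
#'
#' @param spec A \code{fog_psd}, or a list with \code{freq} and \code{power}.
#' @param lo,hi Band edges in Hz, \code{0 <= lo < hi <=} Nyquist.
#' @return Non-negative power.
#' @export
band_power <- function(spec, lo, hi) {
  if (!(lo >= 0 && lo < hi)) stop("invalid band: need 0 <= lo < hi", call. = FALSE)
  band_power_vec(spec$freq, spec$power, lo, hi)
}

# works on a power matrix (n_freq x n_win) too
band_power_vec <- function(freq, power, lo, hi) {
  if (hi > max(freq)) hi <- max(freq)
  if (is.matrix(power)) {
    apply(power, 2, function(p) band_power_vec(freq, p, lo, hi))
  } else {
    inside <- freq > lo & freq < hi
    fgrid <- c(lo, freq[inside], hi)
    pgrid <- c(approx(freq, power, lo)$y, power[inside],
               approx(freq, power, hi)$y)
    sum(diff(fgrid) * (head(pgrid, -1) + tail(pgrid, -1)) / 2)
  }
}

#' Freeze index and freeze ratio of a movement spectrum
#'
#' \code{freeze_index} is the ratio of freeze-band (3--8 Hz) to
#' locomotion-band (0.5--3 Hz) power; it grows without bound as power shifts
#' into the freeze band. \code{freeze_ratio} is the bounded variant
#' P(3--8)/P(0.5--8), lying in [0, 1]. Zero locomotion-band power yields
#' \code{Inf} (flagged for clipping at range normalization).
#'
#' @param spec A \code{fog_psd}.
#' @return Non-negative scalar.
#' @export
freeze_index <- function(spec) {
  loco <- band_power(spec, 0.5, 3)
  frz <- band_power(spec, 3, 8)
  if (loco == 0) return(Inf)
  frz / loco
}

#' @rdname freeze_index
#' @export
freeze_ratio <- function(spec) {
  tot <- band_power(spec, 0.5, 8)
  if (tot == 0) return(0)
  band_power(spec, 3, 8) / tot
}

#' Spectral moments and shape descriptors
#'
#' Dominant (argmax), power-weighted mean and median frequencies, skewness
#' and kurtosis of the normalized spectral distribution, spectral energy,
#' Shannon entropy of the normalized spectrum (scaled to [0, 1] by the log of
#' the bin count) and total/mean/max/std power.
#'
#' @param spec A \code{fog_psd}.
#' @return Named numeric vector.
#' @export
spectral_moments <- function(spec) {
  f <- spec$freq; p <- spec$power
  tot <- sum(p)
  if (tot == 0) stop("all-zero spectrum", call. = FALSE)
  pr <- p / tot
  mean_f <- sum(f * pr)
  cum <- cumsum(pr)
  median_f <- f[which(cum >= 0.5)[1]]
  dom_f <- f[which.max(p)]
  mu2 <- sum((f - mean_f)^2 * pr)
  skew <- if (mu2 > 0) sum((f - mean_f)^3 * pr) / mu2^1.5 else 0
  kurt <- if (mu2 > 0) sum((f - mean_f)^4 * pr) / mu2^2 else 0
  pos <- pr[pr > 0]
  entropy <- -sum(pos * log(pos)) / log(length(p))
  df <- f[2] - f[1]
  c(total_power = tot * df, mean_power = mean(p), max_power = max(p),
    std_power = sd_pop(p), dominant_freq = dom_f, mean_freq = mean_f,
    median_freq = median_f, psd_skewness = skew, psd_kurtosis = kurt,
    spec_energy = sum(p^2) * df, spec_entropy = entropy)
}

# Band-averaged magnitude squared coherence for all channel pairs of a
# window. X_list: list over channels of complex segment-FFT matrices
# (n_freq_full x n_seg) from welch_fft. Returns matrix n_pairs x n_bands.
msc_band_matrix <- function(X_list, fs, seg_len, bands) {
  nf <- seg_len %/% 2 + 1
  freq <- (seq_len(nf) - 1) * fs / seg_len
  n_ch <- length(X_list)
  auto <- lapply(X_list, function(X) rowSums(Mod(X[seq_len(nf), , drop = FALSE])^2))
  pairs <- utils::combn(n_ch, 2)
  out <- matrix(NA_real_, ncol(pairs), length(bands))
  band_idx <- lapply(bands, function(b) which(freq >= b[1] & freq <= b[2]))
  for (pp in seq_len(ncol(pairs))) {
    i <- pairs[1, pp]; j <- pairs[2, pp]
    cross <- rowSums(X_list[[i]][seq_len(nf), , drop = FALSE] *
                       Conj(X_list[[j]][seq_len(nf), , drop = FALSE]))
    msc <- Mod(cross)^2 / (auto[[i]] * auto[[j]])
    out[pp, ] <- vapply(band_idx, function(ix) mean(msc[ix]), 0)
  }
  list(pairs = pairs, msc = out)
}
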