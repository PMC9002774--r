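#' Drop FOG episodes shorter than the detector's time resolution
#'
#' Episodes lasting strictly less than \code{min_len_s} are removed (an
#' episode of exactly \code{min_len_s} is retained). With 3 s windows and
#' 5-epoch majority voting the effective time resolution is about 4 s, so
#' sub-3 s episodes cannot be resolved.
#'
#' @param annotations Data frame with columns \code{subject_id, task_id,
#'   start_s, end_s}.
#' @param min_len_s Minimum episode duration retained, seconds.
#' @return Filtered annotations; the number of removed episodes is attached
#'   as attribute \code{"n_removed"} and reported via \code{message}.
#' @export
exclude_short_episodes <- function(annotations, min_len_s = 3) {
  keep <- (annotations$end_s - annotations$start_s) >= min_len_s
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  if (sum(!keep) > 0)
    message(sprintf("excluded %d episode(s) shorter than %g s",
                    sum(!keep), min_len_s))
  out
}

#' Segment a processed recording into labeled overlapping windows
#'
#' Fixed 3 s windows with 90% overlap (0.3 s hop), anchored at t = 0 of the
#' task. Each window is labeled FOG if strictly more than half of its samples
#' fall inside an annotated episode (ties go to nonFOG). Episodes are treated
#' as half-open intervals \code{[start, end)}.
#'
#' @param recording A processed \code{fog_recording} (all modalities at a
#'   common rate).
#' @param annotations Episode annotations (already filtered by
#'   \code{\link{exclude_short_episodes}} if desired).
#' @param window_len_s Window length, seconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @return Object of class \code{fog_windows}: data frame with columns
#'   \code{subject_id, task_id, start_s, end_s, label} plus attributes
#'   \code{fs}, \code{window_len_s}, \code{overlap}.
#' @export
segment_windows <- function(recording, annotations, window_len_s = 3,
                            overlap = 0.9) {
  fs <- recording$modalities[[1]]$fs
  n_samples <- min(vapply(recording$modalities, function(m) ncol(m$samples), 0))
  win <- as.integer(round(window_len_s * fs))
  hop <- as.integer(round(window_len_s * (1 - overlap) * fs))
  if (hop < 1) stop("overlap too large for this sampling rate", call. = FALSE)
  if (n_samples < win) {
    warning("recording shorter than one window; empty window set")
    out <- data.frame(subject_id = character(0), task_id = character(0),
                      start_s = numeric(0), end_s = numeric(0),
                      label = character(0))
    return(structure(out, fs = fs, window_len_s = window_len_s,
                     overlap = overlap, class = c("fog_windows", "data.frame")))
  }
  starts <- seq.int(0L, n_samples - win, by = hop)
  ann <- annotations[annotations$subject_id == recording$subject_id &
                       annotations$task_id == recording$task_id, , drop = FALSE]
  # FOG indicator on the sample grid (sample i at time (i-1)/fs, [start,end))
  t <- (seq_len(n_samples) - 1) / fs
  fog <- episode_indicator(t, ann)
  cs <- c(0, cumsum(fog))
  counts <- cs[starts + win + 1L] - cs[starts + 1L]
  label <- ifelse(counts > win / 2, "FOG", "nonFOG")
  out <- data.frame(subject_id = recording$subject_id,
                    task_id = recording$task_id,
                    start_s = starts / fs,
                    end_s = starts / fs + window_len_s,
                    label = label)
  structure(out, fs = fs, window_len_s = window_len_s, overlap = overlap,
            class = c("fog_windows", "data.frame"))
}

#' Label a single window interval against episode annotations
#'
#' Majority-of-samples rule at the given sampling rate: FOG iff strictly more
#' than half of the window's samples lie inside an episode.
#'
#' @param start_s,end_s Window interval, seconds.
#' @param annotations Data frame with \code{start_s, end_s} episode intervals.
#' @param fs Sampling rate used for the sample grid.
#' @return \code{"FOG"} or \code{"nonFOG"}.
#' @export
label_window <- function(start_s, end_s, annotations, fs = 500) {
  n <- as.integer(round((end_s - start_s) * fs))
  t <- start_s + (seq_len(n) - 1) / fs
  inside <- episode_indicator(t, annotations)
  if (sum(inside) > n / 2) "FOG" else "nonFOG"
}
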