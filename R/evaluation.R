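# Window-level confusion metrics, majority-vote smoothing and episode-level
# detection accounting.

#' Confusion counts and classification metrics
#'
#' TP counts windows labeled FOG and predicted FOG; TN, FP, FN accordingly.
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), accuracy = (TP+TN)/total, F-score = 2*Prec*Sens/(Prec+Sens).
#' Metrics with zero denominators are reported as \code{NA}, never coerced to
#' 0.
#'
#' @param pred,truth Aligned 0/1 (or "FOG"/"nonFOG") vectors.
#' @return Object of class \code{fog_eval} with the four counts and five
#'   metrics.
#' @export
confusion_and_metrics <- function(pred, truth) {
  pred <- as_binary(pred); truth <- as_binary(truth)
  stopifnot(length(pred) == length(truth))
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn); spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp); acc <- div(tp + tn, tp + tn + fp + fn)
  f <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
  else 2 * prec * sens / (prec + sens)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = sens, specificity = spec, precision = prec,
                 accuracy = acc, f_score = f),
            class = "fog_eval")
}

#' @export
print.fog_eval <- function(x, ...) {
  cat(sprintf("windows: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("sensitivity %.3f | specificity %.3f | precision %.3f | accuracy %.3f | F %.3f\n",
              x$sensitivity, x$specificity, x$precision, x$accuracy, x$f_score))
  invisible(x)
}

#' Majority-vote smoothing of a prediction stream
#'
#' Each position is replaced by the majority label of the centered
#' \code{span}-window neighbourhood (5 windows, about 4 s at 3 s windows with
#' 90% overlap). At the stream edges the neighbourhood shrinks to the
#' available windows. Constant streams are fixed points; isolated
#' single-window flips are removed.
#'
#' @param pred 0/1 prediction vector ordered by window start within one task.
#' @param span Neighbourhood size (odd).
#' @return Smoothed 0/1 vector of the same length.
#' @export
majority_vote <- function(pred, span = 5) {
  pred <- as_binary(pred)
  n <- length(pred)
  if (n == 0) return(pred)
  k <- span %/% 2
  cs <- c(0, cumsum(pred))
  lo <- pmax(1L, seq_len(n) - k); hi <- pmin(n, seq_len(n) + k)
  ones <- cs[hi + 1L] - cs[lo]
  width <- hi - lo + 1L
  as.numeric(ones > width / 2)
}

# smooth predictions task-by-task following window order
majority_vote_by_task <- function(pred, subjects, tasks, starts, span = 5) {
  out <- pred
  for (key in unique(paste(subjects, tasks))) {
    ix <- which(paste(subjects, tasks) == key)
    ix <- ix[order(starts[ix])]
    out[ix] <- majority_vote(pred[ix], span)
  }
  out
}

#' Episode-level detection tally
#'
#' An annotated episode counts as detected when at least one FOG-predicted
#' window (after majority-vote smoothing) overlaps the episode interval by
#' more than \code{min_overlap_s} seconds. Annotations are expected to be
#' pre-filtered by \code{\link{exclude_short_episodes}}.
#'
#' @param pred Smoothed 0/1 predictions aligned with \code{windows}.
#' @param windows A \code{fog_windows} data frame.
#' @param annotations Episode annotations.
#' @param min_overlap_s Minimal window/episode overlap to count, seconds
#'   (default 0: any positive overlap).
#' @return List with \code{episode_total}, \code{episode_detected} and a
#'   per-episode data frame.
#' @export
episode_detection <- function(pred, windows, annotations, min_overlap_s = 0) {
  pred <- as_binary(pred)
  det <- logical(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    cand <- which(windows$subject_id == a$subject_id &
                    windows$task_id == a$task_id & pred == 1)
    if (length(cand) == 0) next
    ov <- pmin(windows$end_s[cand], a$end_s) - pmax(windows$start_s[cand], a$start_s)
    det[i] <- any(ov > min_overlap_s)
  }
  tab <- cbind(annotations, detected = det)
  list(episode_total = nrow(annotations), episode_detected = sum(det),
       episodes = tab)
}

#' Full evaluation report of a fitted detector
#'
#' Window-level confusion metrics before and after majority-vote smoothing,
#' plus the episode-level detection tally (post-smoothing).
#'
#' @param fit A \code{fog_sia} or \code{fog_sda} object carrying window
#'   metadata (subjects, tasks, starts for SIA).
#' @param windows The \code{fog_windows} the features were extracted on.
#' @param annotations Filtered episode annotations.
#' @param span Majority-vote span.
#' @return Object of class \code{fog_report}.
#' @export
evaluate_fit <- function(fit, windows, annotations, span = 5) {
  pred <- fit$predictions
  keep <- !is.na(pred)
  smoothed <- majority_vote_by_task(pred[keep], windows$subject_id[keep],
                                    windows$task_id[keep],
                                    windows$start_s[keep], span)
  raw <- confusion_and_metrics(pred[keep], fit$labels[keep])
  mv <- confusion_and_metrics(smoothed, fit$labels[keep])
  ep <- episode_detection(smoothed, windows[keep, , drop = FALSE], annotations)
  structure(list(raw = raw, smoothed = mv, episode_total = ep$episode_total,
                 episode_detected = ep$episode_detected,
                 episodes = ep$episodes, mode = fit$mode, mv_applied = TRUE,
                 span = span),
            class = "fog_report")
}

#' @export
print.fog_report <- function(x, ...) {
  cat(sprintf("FOG evaluation report (%s)\n", x$mode))
  cat("raw window predictions:\n  "); print(x$raw)
  cat(sprintf("after %d-window majority vote:\n  ", x$span)); print(x$smoothed)
  cat(sprintf("episodes detected: %d / %d (%.1f%%)\n", x$episode_detected,
              x$episode_total,
              100 * x$episode_detected / max(x$episode_total, 1)))
  invisible(x)
}
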