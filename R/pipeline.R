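# End-to-end orchestration: simulate -> preprocess -> window -> features ->
# select/train (SIA or SDA) -> evaluate, with reproducible artifacts.

#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults matching the analysis design:
#' 3 s windows at 90% overlap, selection thresholds 0.35 (SIA) / 0.4 (SDA)
#' with 0.86 redundancy pruning and p < 0.05, 5-epoch majority voting, 500 Hz
#' analysis rate, 3 s minimum episode duration.
#'
#' @param params Cohort parameters (\code{\link{cohort_params}}).
#' @param mode \code{"sia"} or \code{"sda"}.
#' @param sensors Sensor groups to extract features from.
#' @param grid Hyperparameter grid.
#' @param window_len_s,overlap Windowing parameters.
#' @param min_episode_s Episodes shorter than this are excluded.
#' @param mv_span Majority-vote span in windows.
#' @param seed Run seed (also used for the cohort unless \code{params} sets
#'   its own).
#' @return Object of class \code{fog_config}.
#' @export
fog_config <- function(params = cohort_params(), mode = c("sia", "sda"),
                       sensors = "tibia", grid = fog_grid("compact"),
                       window_len_s = 3, overlap = 0.9, min_episode_s = 3,
                       mv_span = 5, seed = params$seed) {
  structure(list(params = params, mode = match.arg(mode), sensors = sensors,
                 grid = grid, window_len_s = window_len_s, overlap = overlap,
                 min_episode_s = min_episode_s, mv_span = mv_span,
                 seed = as.integer(seed)),
            class = "fog_config")
}

#' Run the full FOG detection pipeline
#'
#' Simulates (or ingests) a cohort, preprocesses every recording, segments
#' and labels windows, extracts features, fits the subject-independent or
#' subject-dependent detector and evaluates it at window and episode level.
#' When \code{out_dir} is given, every intermediate artifact (windows,
#' feature matrix, selection tables, fold results, evaluation report, the
#' resolved configuration and a log) is written as CSV/JSON, and a rerun with
#' the same configuration reproduces them byte-identically.
#'
#' @param config A \code{\link{fog_config}}.
#' @param cohort Optional pre-built cohort (list of recordings +
#'   annotations); simulated from \code{config$params} when \code{NULL}.
#' @param out_dir Optional artifact directory.
#' @return Object of class \code{fog_run}: list with the fitted model
#'   (\code{fit}), \code{report}, \code{windows}, \code{features},
#'   \code{annotations} and \code{config}.
#' @export
run_pipeline <- function(config, cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "fog_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(cohort)) {
    say("simulate: %d subjects x %d tasks x %gs",
        config$params$n_subjects, config$params$tasks_per_subject,
        config$params$task_duration_s)
    cohort <- stage("simulate", simulate_cohort(config$params))
  }
  say("preprocess: %d recordings", length(cohort$recordings))
  processed <- stage("preprocess", lapply(cohort$recordings, preprocess_recording))
  ann <- stage("annotations",
               suppressMessages(exclude_short_episodes(cohort$annotations,
                                                       config$min_episode_s)))
  say("windows: %g s / %.0f%% overlap; %d episodes retained (%d excluded)",
      config$window_len_s, 100 * config$overlap, nrow(ann),
      attr(ann, "n_removed"))
  win_list <- list(); feat_list <- list()
  for (rec in processed) {
    w <- stage("windowing", segment_windows(rec, ann, config$window_len_s,
                                            config$overlap))
    f <- stage("features", extract_features(rec, w, sensors = config$sensors))
    win_list[[length(win_list) + 1]] <- w
    feat_list[[length(feat_list) + 1]] <- f$x
  }
  windows <- do.call(rbind, win_list)
  attr(windows, "fs") <- attr(win_list[[1]], "fs")
  attr(windows, "window_len_s") <- config$window_len_s
  attr(windows, "overlap") <- config$overlap
  x <- do.call(rbind, feat_list)
  y <- as_binary(windows$label)
  say("features: %d windows x %d columns (FOG prevalence %.1f%%)",
      nrow(x), ncol(x), 100 * mean(y))
  fit <- if (config$mode == "sia") {
    stage("train", fog_sia(x, y, subjects = windows$subject_id,
                           tasks = windows$task_id, grid = config$grid,
                           starts = windows$start_s))
  } else {
    subj <- unique(windows$subject_id)
    if (length(subj) > 1)
      say("sda: fitting subject %s only (first of %d)", subj[1], length(subj))
    ix <- windows$subject_id == subj[1]
    fit1 <- stage("train", fog_sda(x[ix, , drop = FALSE], y[ix],
                                   tasks = windows$task_id[ix],
                                   grid = config$grid, seed = config$seed))
    fit1$subjects <- windows$subject_id[ix]
    fit1
  }
  eval_windows <- if (config$mode == "sda")
    windows[windows$subject_id == unique(windows$subject_id)[1], , drop = FALSE]
  else windows
  eval_ann <- ann[ann$subject_id %in% eval_windows$subject_id, , drop = FALSE]
  report <- stage("evaluate", evaluate_fit(fit, eval_windows, eval_ann,
                                           span = config$mv_span))
  say("evaluation: F %.3f (raw) -> %.3f (smoothed); episodes %d/%d",
      report$raw$f_score, report$smoothed$f_score,
      report$episode_detected, report$episode_total)
  run <- structure(list(fit = fit, report = report, windows = windows,
                        features = x, annotations = ann, config = config,
                        log = log_lines),
                   class = "fog_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.fog_run <- function(x, ...) {
  print(x$fit)
  print(x$report)
  invisible(x)
}

# serialize run artifacts (CSV/JSON) into a directory
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- as.data.frame(run$windows)
  write.csv(w, file.path(out_dir, "windows.csv"), row.names = FALSE)
  write.csv(cbind(w[, c("subject_id", "task_id", "start_s")],
                  as.data.frame(run$features)),
            file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(run$annotations, file.path(out_dir, "annotations.csv"),
            row.names = FALSE)
  sel_rows <- lapply(names(run$fit$folds), function(nm) {
    s <- as.data.frame(run$fit$folds[[nm]]$selection)
    s$fold <- nm
    s
  })
  write.csv(do.call(rbind, sel_rows), file.path(out_dir, "selection.csv"),
            row.names = FALSE)
  folds <- do.call(rbind, lapply(names(run$fit$folds), function(nm) {
    f <- run$fit$folds[[nm]]
    data.frame(fold = nm, model = format_cell(f$cell),
               n_features = length(f$features),
               accuracy = f$metrics$accuracy, f_score = f$metrics$f_score)
  }))
  write.csv(folds, file.path(out_dir, "fold_results.csv"), row.names = FALSE)
  report <- run$report
  jsonlite::write_json(list(
    mode = report$mode, mv_applied = report$mv_applied, span = report$span,
    raw = unclass(report$raw), smoothed = unclass(report$smoothed),
    episode_total = report$episode_total,
    episode_detected = report$episode_detected),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  cfg <- run$config
  jsonlite::write_json(list(
    mode = cfg$mode, sensors = cfg$sensors, window_len_s = cfg$window_len_s,
    overlap = cfg$overlap, min_episode_s = cfg$min_episode_s,
    mv_span = cfg$mv_span, seed = cfg$seed,
    params = unclass(cfg$params), grid = cfg$grid),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
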