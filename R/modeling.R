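# SVM / kNN training with hyperparameter search over the published ranges,
# nested leave-one-subject-out (subject-independent) and 10-fold CV +
# leave-one-task-out (subject-dependent) procedures.

#' Hyperparameter grid for the SVM and kNN classifiers
#'
#' The search space covers kernels linear/quadratic/cubic/gaussian with
#' kernel scale and cost in [0.1, 100] for the SVM, and 1--180 neighbours
#' with cityblock / euclidean / squared-euclidean metrics and equal / inverse
#' / squared-inverse distance weights for kNN. The \code{"full"} preset
#' samples the continuous ranges at 5 log-spaced points (154 cells); the
#' \code{"compact"} preset is a 4-cell subset spanning both model families,
#' used for the desk-scale synthetic study.
#'
#' @param preset \code{"compact"} or \code{"full"}.
#' @return Data frame of grid cells with columns \code{model, kernel,
#'   kernel_scale, cost, k, metric, weight}.
#' @export
fog_grid <- function(preset = c("compact", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    logpts <- 10^seq(log10(0.1), log10(100), length.out = 5)
    svm <- expand.grid(model = "svm",
                       kernel = c("linear", "quadratic", "cubic", "gaussian"),
                       kernel_scale = logpts, cost = logpts,
                       k = NA, metric = NA, weight = NA,
                       stringsAsFactors = FALSE)
    knn <- expand.grid(model = "knn", kernel = NA, kernel_scale = NA, cost = NA,
                       k = c(1, 5, 15, 45, 90, 180),
                       metric = c("cityblock", "euclidean", "squared-euclidean"),
                       weight = c("equal", "inverse", "squared-inverse"),
                       stringsAsFactors = FALSE)
  } else {
    svm <- data.frame(model = "svm", kernel = c("linear", "gaussian"),
                      kernel_scale = c(1, 1), cost = c(1, 10),
                      k = NA, metric = NA, weight = NA)
    knn <- data.frame(model = "knn", kernel = NA, kernel_scale = NA, cost = NA,
                      k = c(5, 15), metric = "euclidean", weight = "equal")
  }
  rbind(svm, knn)
}

#' Train one classifier configuration and predict
#'
#' SVM via libsvm (kernels: linear; polynomial degree 2/3 with gamma =
#' 1/kernel_scale; radial with gamma = 1/kernel_scale^2) or a weighted kNN
#' with the cityblock, euclidean or squared-euclidean metric and equal,
#' inverse-distance or squared-inverse-distance voting. Deterministic given
#' its inputs; prediction ties go to the negative class.
#'
#' @param cell One row of \code{\link{fog_grid}}.
#' @param train_x,train_y Training matrix and binary labels.
#' @param test_x Matrix to predict.
#' @return Numeric 0/1 predictions for \code{test_x} rows.
#' @export
fit_predict <- function(cell, train_x, train_y, test_x) {
  train_y <- as_binary(train_y)
  if (length(unique(train_y)) < 2)
    stop("training set contains a single class", call. = FALSE)
  if (cell$model == "svm") {
    args <- switch(as.character(cell$kernel),
                   linear = list(kernel = "linear"),
                   quadratic = list(kernel = "polynomial", degree = 2,
                                    gamma = 1 / cell$kernel_scale, coef0 = 1),
                   cubic = list(kernel = "polynomial", degree = 3,
                                gamma = 1 / cell$kernel_scale, coef0 = 1),
                   gaussian = list(kernel = "radial",
                                   gamma = 1 / cell$kernel_scale^2))
    fit <- do.call(e1071::svm,
                   c(list(x = train_x, y = factor(train_y, levels = c(0, 1)),
                          cost = cell$cost, scale = FALSE), args))
    as.numeric(as.character(predict(fit, test_x)))
  } else {
    knn_predict(train_x, train_y, test_x, k = cell$k, metric = cell$metric,
                weight = cell$weight)
  }
}

#' Weighted k-nearest-neighbour prediction
#'
#' @param train_x,train_y Training matrix and 0/1 labels.
#' @param test_x Matrix to predict.
#' @param k Number of neighbours.
#' @param metric \code{"cityblock"}, \code{"euclidean"} or
#'   \code{"squared-euclidean"} (the latter two always rank neighbours
#'   identically).
#' @param weight \code{"equal"}, \code{"inverse"} (1/d) or
#'   \code{"squared-inverse"} (1/d^2); zero distances dominate their
#'   neighbourhood.
#' @return Numeric 0/1 predictions (vote ties go to 0).
#' @export
knn_predict <- function(train_x, train_y, test_x, k, metric = "euclidean",
                        weight = "equal") {
  train_y <- as_binary(train_y)
  k <- min(k, nrow(train_x))
  if (metric == "cityblock") {
    D <- matrix(0, nrow(train_x), nrow(test_x))
    for (j in seq_len(ncol(train_x)))
      D <- D + abs(outer(train_x[, j], test_x[, j], "-"))
  } else {
    sq <- outer(rowSums(train_x^2), rowSums(test_x^2), "+") -
      2 * tcrossprod(train_x, test_x)
    sq[sq < 0] <- 0
    D <- if (metric == "squared-euclidean") sq else sqrt(sq)
  }
  apply(D, 2, function(d) {
    nb <- order(d)[seq_len(k)]
    dd <- d[nb]
    w <- switch(weight,
                equal = rep(1, k),
                inverse = 1 / pmax(dd, .Machine$double.eps),
                `squared-inverse` = 1 / pmax(dd, .Machine$double.eps)^2)
    if (any(dd == 0) && weight != "equal") w <- as.numeric(dd == 0)
    score <- sum(w * train_y[nb]) / sum(w)
    as.numeric(score > 0.5)
  })
}

#' Model-choice rule between candidate classifiers
#'
#' If one candidate maximizes both accuracy and F-score it is chosen;
#' otherwise the candidate with the maximal F-score wins. Exact ties are
#' broken by candidate name (lexicographically first).
#'
#' @param candidates Data frame with columns \code{id}, \code{accuracy},
#'   \code{f_score}.
#' @return The chosen \code{id}.
#' @export
choose_model <- function(candidates) {
  stopifnot(nrow(candidates) >= 1)
  candidates <- candidates[order(candidates$id), , drop = FALSE]
  best_acc <- candidates$id[which(candidates$accuracy == max(candidates$accuracy))]
  best_f <- candidates$id[which(candidates$f_score == max(candidates$f_score))]
  both <- intersect(best_acc, best_f)
  if (length(both) > 0) both[1] else best_f[1]
}

# metrics of a prediction vector (window-level); F treated as 0 for ranking
# when undefined
fold_metrics <- function(pred, truth) {
  r <- confusion_and_metrics(pred, truth)
  c(accuracy = r$accuracy, f_score = if (is.na(r$f_score)) 0 else r$f_score)
}

# ---- subject-independent algorithm (nested LOSO) ---------------------------

#' Fit the subject-independent FOG detector (nested leave-one-subject-out)
#'
#' For each of the N outer folds, one subject is held out for testing.
#' Feature selection (correlation filter at |r| >= 0.35 + redundancy pruning)
#' and range normalization are fitted on the N-1 training subjects only. An
#' inner leave-one-subject-out loop over those N-1 subjects scores every grid
#' cell; the best SVM cell and best kNN cell (mean inner F-score) compete
#' under the accuracy/F-score model-choice rule; the winner is refit on all
#' N-1 subjects and applied to the held-out subject. A consensus model (the
#' modal fold configuration refit on all subjects) is stored for
#' \code{predict}.
#'
#' @param x Feature matrix (windows x features, named columns), un-normalized.
#' @param y Window labels (0/1 or "FOG"/"nonFOG").
#' @param subjects Subject id per window.
#' @param tasks Optional task id per window (kept for downstream smoothing).
#' @param grid Hyperparameter grid, see \code{\link{fog_grid}}.
#' @param r_thresh,cross_thresh Selection thresholds.
#' @param starts Optional window start times (kept for downstream smoothing).
#' @return Object of class \code{fog_sia} with per-fold results, aggregate
#'   window predictions and metrics.
#' @export
fog_sia <- function(x, y, subjects, tasks = NULL, grid = fog_grid("compact"),
                    r_thresh = 0.35, cross_thresh = 0.86, starts = NULL) {
  y <- as_binary(y)
  subj_ids <- unique(subjects)
  if (length(subj_ids) < 3) stop("need at least 3 subjects", call. = FALSE)
  folds <- list()
  pred_all <- rep(NA_real_, length(y))
  audit <- list()
  for (s in subj_ids) {
    test_idx <- which(subjects == s)
    train_idx <- which(subjects != s)
    sel <- select_features(x[train_idx, , drop = FALSE], y[train_idx],
                           mode = "SIA", r_thresh = r_thresh,
                           cross_thresh = cross_thresh)
    feats <- attr(sel, "retained")
    if (length(feats) == 0)
      stop(sprintf("no features retained in fold %s", s), call. = FALSE)
    norm <- range_normalize(x[train_idx, feats, drop = FALSE])
    xtr <- norm$x
    xte <- range_normalize(x[test_idx, feats, drop = FALSE], norm$ranges)$x
    inner_subj <- unique(subjects[train_idx])
    usable <- vapply(inner_subj, function(v)
      length(unique(y[train_idx][subjects[train_idx] == v])) == 2, TRUE)
    if (any(!usable))
      warning(sprintf("fold %s: inner subject(s) %s lack both classes; excluded from validation",
                      s, paste(inner_subj[!usable], collapse = ", ")))
    val_subj <- inner_subj[usable]
    cell_scores <- matrix(NA_real_, nrow(grid), 2,
                          dimnames = list(NULL, c("accuracy", "f_score")))
    inner_scores <- array(NA_real_, c(nrow(grid), length(val_subj), 2))
    for (vi in seq_along(val_subj)) {
      v <- val_subj[vi]
      itr <- which(subjects[train_idx] != v)
      iva <- which(subjects[train_idx] == v)
      for (g in seq_len(nrow(grid))) {
        p <- fit_predict(grid[g, ], xtr[itr, , drop = FALSE],
                         y[train_idx][itr], xtr[iva, , drop = FALSE])
        inner_scores[g, vi, ] <- fold_metrics(p, y[train_idx][iva])
      }
    }
    cell_scores[, "accuracy"] <- rowMeans(inner_scores[, , 1, drop = FALSE])
    cell_scores[, "f_score"] <- rowMeans(inner_scores[, , 2, drop = FALSE])
    best_cell_of <- function(fam) {
      ix <- which(grid$model == fam)
      ix[order(-cell_scores[ix, "f_score"], -cell_scores[ix, "accuracy"])][1]
    }
    cand_ix <- vapply(unique(grid$model), best_cell_of, 0L)
    cand <- data.frame(id = unique(grid$model),
                       accuracy = cell_scores[cand_ix, "accuracy"],
                       f_score = cell_scores[cand_ix, "f_score"])
    chosen_fam <- choose_model(cand)
    cell <- grid[cand_ix[match(chosen_fam, unique(grid$model))], ]
    pred <- fit_predict(cell, xtr, y[train_idx], xte)
    pred_all[test_idx] <- pred
    folds[[s]] <- list(test_subject = s, cell = cell,
                       selection = sel, features = feats,
                       n_inner = length(val_subj),
                       inner_scores = cell_scores,
                       metrics = confusion_and_metrics(pred, y[test_idx]))
    audit[[s]] <- list(train = train_idx, test = test_idx)
  }
  out <- list(folds = folds, predictions = pred_all, labels = y,
              subjects = subjects, tasks = tasks, starts = starts,
              metrics = confusion_and_metrics(pred_all, y),
              grid = grid, audit = audit, mode = "SIA")
  # consensus: modal configuration refit on everything (used by predict())
  cfgs <- vapply(folds, function(f) paste(unlist(f$cell), collapse = "|"), "")
  modal <- names(sort(table(cfgs), decreasing = TRUE))[1]
  modal_cell <- folds[[which(cfgs == modal)[1]]]$cell
  sel_all <- select_features(x, y, mode = "SIA", r_thresh = r_thresh,
                             cross_thresh = cross_thresh)
  feats_all <- attr(sel_all, "retained")
  norm_all <- range_normalize(x[, feats_all, drop = FALSE])
  out$consensus <- list(cell = modal_cell, selection = sel_all,
                        features = feats_all, ranges = norm_all$ranges,
                        train_x = norm_all$x, train_y = y)
  class(out) <- "fog_sia"
  out
}

#' @export
print.fog_sia <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Subject-independent FOG detector (nested LOSO, %d subjects)\n",
              length(x$folds)))
  cat(sprintf("  aggregate: accuracy %.3f | sensitivity %.3f | specificity %.3f | F %.3f\n",
              m$accuracy, m$sensitivity, m$specificity, m$f_score))
  cat(sprintf("  consensus model: %s\n", format_cell(x$consensus$cell)))
  invisible(x)
}

format_cell <- function(cell) {
  if (cell$model == "svm")
    sprintf("SVM (%s kernel, scale %g, cost %g)", cell$kernel,
            cell$kernel_scale, cell$cost)
  else
    sprintf("kNN (k=%d, %s, %s weights)", cell$k, cell$metric, cell$weight)
}

#' @export
summary.fog_sia <- function(object, ...) {
  per_fold <- do.call(rbind, lapply(object$folds, function(f)
    data.frame(subject = f$test_subject, model = format_cell(f$cell),
               n_features = length(f$features),
               accuracy = f$metrics$accuracy, f_score = f$metrics$f_score)))
  rownames(per_fold) <- NULL
  structure(list(per_fold = per_fold, aggregate = object$metrics),
            class = "summary.fog_sia")
}

#' @export
print.summary.fog_sia <- function(x, ...) {
  cat("Per-fold (held-out subject) results:\n")
  print(x$per_fold, row.names = FALSE)
  cat("\nAggregate window-level metrics:\n")
  print(x$aggregate)
  invisible(x)
}

#' Predict FOG labels for new windows with a fitted detector
#'
#' Uses the consensus model: the modal fold configuration refit on all
#' training subjects, with the all-data feature selection and normalization.
#'
#' @param object A \code{fog_sia} fit.
#' @param newdata Feature matrix with the same column names as the training
#'   matrix.
#' @param ... Unused.
#' @return Numeric 0/1 predictions.
#' @export
predict.fog_sia <- function(object, newdata, ...) {
  cns <- object$consensus
  xte <- range_normalize(newdata[, cns$features, drop = FALSE], cns$ranges)$x
  fit_predict(cns$cell, cns$train_x, cns$train_y, xte)
}

#' @export
plot.fog_sia <- function(x, ...) {
  f <- vapply(x$folds, function(f) f$metrics$f_score, 0)
  graphics::barplot(f, names.arg = names(x$folds), ylim = c(0, 1),
                    ylab = "F-score", xlab = "held-out subject",
                    main = "Per-subject test F-score (LOSO)", ...)
  graphics::abline(h = x$metrics$f_score, lty = 2)
  invisible(x)
}

# ---- subject-dependent algorithm (10-fold CV + LOTO) -----------------------

#' Fit the subject-dependent FOG detector for one subject
#'
#' Leave-one-task-out over the subject's tasks: for each held-out task,
#' features are selected (|r| >= 0.4) and normalized on the remaining tasks,
#' hyperparameters are chosen by stratified 10-fold cross-validation on those
#' training windows, and the winning configuration is refit and applied to
#' the held-out task. Subjects with FOG windows in fewer than two tasks are
#' rejected.
#'
#' @param x Feature matrix of the subject's windows.
#' @param y Window labels.
#' @param tasks Task id per window.
#' @param grid Hyperparameter grid.
#' @param r_thresh,cross_thresh Selection thresholds.
#' @param n_folds CV folds for the validation phase.
#' @param seed Seed for the fold assignment.
#' @return Object of class \code{fog_sda}.
#' @export
fog_sda <- function(x, y, tasks, grid = fog_grid("compact"), r_thresh = 0.4,
                    cross_thresh = 0.86, n_folds = 10, seed = 1) {
  y <- as_binary(y)
  task_ids <- unique(tasks)
  fog_tasks <- task_ids[vapply(task_ids, function(tt) any(y[tasks == tt] == 1), TRUE)]
  if (length(fog_tasks) < 2)
    stop("subject has FOG windows in fewer than 2 tasks; skipped", call. = FALSE)
  folds <- list()
  pred_all <- rep(NA_real_, length(y))
  audit <- list()
  for (tt in task_ids) {
    test_idx <- which(tasks == tt)
    train_idx <- which(tasks != tt)
    if (length(unique(y[train_idx])) < 2) {
      warning(sprintf("task %s: training tasks lack both classes; fold skipped", tt))
      next
    }
    sel <- select_features(x[train_idx, , drop = FALSE], y[train_idx],
                           mode = "SDA", r_thresh = r_thresh,
                           cross_thresh = cross_thresh)
    feats <- attr(sel, "retained")
    if (length(feats) == 0) {
      warning(sprintf("task %s: no features retained; fold skipped", tt))
      next
    }
    norm <- range_normalize(x[train_idx, feats, drop = FALSE])
    xtr <- norm$x
    xte <- range_normalize(x[test_idx, feats, drop = FALSE], norm$ranges)$x
    fold_id <- with_seed(child_seed(seed, match(tt, task_ids)),
                         stratified_folds(y[train_idx], n_folds))
    cell_scores <- matrix(0, nrow(grid), 2,
                          dimnames = list(NULL, c("accuracy", "f_score")))
    for (g in seq_len(nrow(grid))) {
      sc <- vapply(seq_len(max(fold_id)), function(fi) {
        itr <- which(fold_id != fi); iva <- which(fold_id == fi)
        if (length(unique(y[train_idx][itr])) < 2) return(c(NA, NA))
        p <- fit_predict(grid[g, ], xtr[itr, , drop = FALSE],
                         y[train_idx][itr], xtr[iva, , drop = FALSE])
        fold_metrics(p, y[train_idx][iva])
      }, numeric(2))
      cell_scores[g, ] <- rowMeans(sc, na.rm = TRUE)
    }
    best_cell_of <- function(fam) {
      ix <- which(grid$model == fam)
      ix[order(-cell_scores[ix, "f_score"], -cell_scores[ix, "accuracy"])][1]
    }
    cand_ix <- vapply(unique(grid$model), best_cell_of, 0L)
    cand <- data.frame(id = unique(grid$model),
                       accuracy = cell_scores[cand_ix, "accuracy"],
                       f_score = cell_scores[cand_ix, "f_score"])
    cell <- grid[cand_ix[match(choose_model(cand), unique(grid$model))], ]
    pred <- fit_predict(cell, xtr, y[train_idx], xte)
    pred_all[test_idx] <- pred
    folds[[tt]] <- list(test_task = tt, cell = cell, selection = sel,
                        features = feats,
                        metrics = confusion_and_metrics(pred, y[test_idx]))
    audit[[tt]] <- list(train = train_idx, test = test_idx)
  }
  eval_idx <- which(!is.na(pred_all))
  out <- list(folds = folds, predictions = pred_all, labels = y, tasks = tasks,
              metrics = confusion_and_metrics(pred_all[eval_idx], y[eval_idx]),
              grid = grid, audit = audit, mode = "SDA")
  class(out) <- "fog_sda"
  out
}

#' @export
print.fog_sda <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Subject-dependent FOG detector (10-fold CV + LOTO, %d tasks)\n",
              length(x$folds)))
  cat(sprintf("  aggregate: accuracy %.3f | sensitivity %.3f | specificity %.3f | F %.3f\n",
              m$accuracy, m$sensitivity, m$specificity, m$f_score))
  invisible(x)
}

#' @export
summary.fog_sda <- function(object, ...) {
  per_fold <- do.call(rbind, lapply(object$folds, function(f)
    data.frame(task = f$test_task, model = format_cell(f$cell),
               n_features = length(f$features),
               accuracy = f$metrics$accuracy, f_score = f$metrics$f_score)))
  rownames(per_fold) <- NULL
  structure(list(per_fold = per_fold, aggregate = object$metrics),
            class = "summary.fog_sda")
}

#' @export
print.summary.fog_sda <- function(x, ...) {
  cat("Per-task (held-out) results:\n")
  print(x$per_fold, row.names = FALSE)
  cat("\nAggregate window-level metrics:\n")
  print(x$aggregate)
  invisible(x)
}

# stratified fold assignment: each class spread as evenly as possible; folds
# shrink when a class has fewer members than folds
stratified_folds <- function(y, n_folds) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    ix <- ix[sample.int(length(ix))]
    id[ix] <- rep_len(seq_len(n_folds), length(ix))
  }
  id
}

#' Audit a fitted detector for train/test contamination
#'
#' Verifies that no window used to fit any stage of a fold (selection,
#' normalization, hyperparameter search, final training) appears in that
#' fold's test set.
#'
#' @param fit A \code{fog_sia} or \code{fog_sda} object.
#' @return \code{TRUE} invisibly; stops on contamination.
#' @export
leakage_audit <- function(fit) {
  for (nm in names(fit$audit)) {
    a <- fit$audit[[nm]]
    if (length(intersect(a$train, a$test)) > 0)
      stop(sprintf("leakage detected in fold %s", nm), call. = FALSE)
  }
  invisible(TRUE)
}
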