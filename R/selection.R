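# Correlation-based filter feature selection with redundancy pruning.
# SIA mode retains features with |r| >= 0.35 against the binary label,
# SDA mode with |r| >= 0.4; both prune redundant survivors (|cross r| >= 0.86)
# keeping the member most correlated with the label.

# p-value of a Pearson correlation via the exact t transform (n - 2 df)
pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * pt(t, df = n - 2, lower.tail = FALSE)
}

# thresholds are inclusive; a small tolerance keeps exactly-at-boundary
# features on the retained side despite floating-point rounding
GE_TOL <- 1e-12

#' Correlation-based feature retention
#'
#' Computes the Pearson (point-biserial) correlation of each feature column
#' with the 0/1 window label and retains features with \code{|r| >= r_thresh}
#' and p-value below \code{p_thresh}. Absolute correlation is used: features
#' that decrease during FOG are as informative as ones that increase.
#'
#' @param x Numeric matrix (windows x features) with column names.
#' @param y Binary labels (0/1, logical, or factor with two levels).
#' @param r_thresh Correlation threshold (0.35 for the subject-independent
#'   variant, 0.4 for the subject-dependent one).
#' @param p_thresh Significance threshold.
#' @return Object of class \code{fog_selection}: data frame (feature, r, p,
#'   retained, replaced_by) plus attribute \code{retained} (character).
#' @export
correlation_select <- function(x, y, r_thresh = 0.35, p_thresh = 0.05) {
  y <- as_binary(y)
  if (length(unique(y)) < 2)
    stop("labels contain a single class; selection impossible", call. = FALSE)
  n <- nrow(x)
  sds <- apply(x, 2, sd_pop)
  r <- rep(NA_real_, ncol(x))
  ok <- sds > 0 & apply(x, 2, function(c) all(is.finite(c)))
  r[ok] <- as.vector(cor(x[, ok, drop = FALSE], y))
  p <- ifelse(is.na(r), 1, pearson_p(r, n))
  retained <- !is.na(r) & abs(r) >= r_thresh - GE_TOL & p < p_thresh
  out <- data.frame(feature = colnames(x), r = r, p = p, retained = retained,
                    replaced_by = NA_character_, stringsAsFactors = FALSE)
  structure(out, retained = colnames(x)[retained],
            class = c("fog_selection", "data.frame"))
}

#' Prune redundant features from a correlation-based selection
#'
#' Greedy pass in descending \code{|r|} (ties broken by feature name): each
#' surviving feature claims and removes every not-yet-claimed feature whose
#' absolute pairwise correlation with it is at least \code{cross_thresh}, so
#' within any redundant group only the member with maximal label correlation
#' survives.
#'
#' @param x Feature matrix used to measure pairwise correlations.
#' @param selection A \code{fog_selection} from
#'   \code{\link{correlation_select}}.
#' @param cross_thresh Redundancy threshold on absolute pairwise correlation.
#' @param groups Optional named character vector mapping feature names to
#'   sensor groups. Each sensor's feature set is treated separately (as it is
#'   through normalization), so redundancy is resolved within a sensor and a
#'   feature can only claim same-group partners; \code{NULL} prunes globally.
#' @return Updated \code{fog_selection}; dropped features carry the name of
#'   the survivor that claimed them in \code{replaced_by}.
#' @export
redundancy_prune <- function(x, selection, cross_thresh = 0.86,
                             groups = NULL) {
  cand <- selection$feature[selection$retained]
  if (length(cand) <= 1) return(selection)
  sub <- x[, cand, drop = FALSE]
  cc <- abs(cor(sub))
  rr <- abs(selection$r[match(cand, selection$feature)])
  grp <- if (is.null(groups)) rep("all", length(cand)) else groups[cand]
  ord <- order(-rr, cand)
  alive <- rep(TRUE, length(cand)); names(alive) <- cand
  names(grp) <- cand
  claimed_by <- rep(NA_character_, length(cand)); names(claimed_by) <- cand
  for (i in ord) {
    f <- cand[i]
    if (!alive[f]) next
    redundant <- cand[alive & cc[f, ] >= cross_thresh - GE_TOL & cand != f &
                        grp == grp[f]]
    alive[redundant] <- FALSE
    claimed_by[redundant] <- f
  }
  out <- selection
  drop_idx <- match(cand[!alive], out$feature)
  out$retained[drop_idx] <- FALSE
  out$replaced_by[drop_idx] <- claimed_by[!alive]
  attr(out, "retained") <- out$feature[out$retained]
  out
}

#' One-call feature selection (correlation filter + redundancy pruning)
#'
#' @inheritParams correlation_select
#' @inheritParams redundancy_prune
#' @param mode \code{"SIA"} (threshold 0.35) or \code{"SDA"} (0.4); an
#'   explicit \code{r_thresh} overrides the mode default.
#' @param groups \code{"sensor"} (default) resolves redundancy within each
#'   sensor's feature set, inferred from the \code{sensor.channel.feature}
#'   naming scheme; \code{"none"} prunes across all columns jointly; or a
#'   named character vector giving an explicit grouping.
#' @return A pruned \code{fog_selection}.
#' @export
select_features <- function(x, y, mode = c("SIA", "SDA"), r_thresh = NULL,
                            p_thresh = 0.05, cross_thresh = 0.86,
                            groups = "sensor") {
  mode <- match.arg(mode)
  r_thresh <- r_thresh %||% if (mode == "SIA") 0.35 else 0.4
  if (identical(groups, "sensor")) {
    if (any(grepl(".", colnames(x), fixed = TRUE))) {
      groups <- sub("\\..*$", "", colnames(x))
      names(groups) <- colnames(x)
    } else groups <- NULL  # names carry no sensor scheme: prune globally
  } else if (identical(groups, "none")) groups <- NULL
  sel <- correlation_select(x, y, r_thresh, p_thresh)
  sel <- redundancy_prune(x, sel, cross_thresh, groups = groups)
  attr(sel, "mode") <- mode
  sel
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) return(as.numeric(y == "FOG"))
  as.numeric(y)
}
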