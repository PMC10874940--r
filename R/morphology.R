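#' Empirical ROC curve
#'
#' Exact, unsmoothed ROC for a scalar score where larger values predict the
#' positive class: a case is called positive when `score >= threshold`.
#' Candidate thresholds are `-Inf`, the midpoints between consecutive
#' distinct sorted scores, and `+Inf`, which enumerate every achievable
#' (sensitivity, specificity) operating point.
#'
#' @param scores Finite numeric scores.
#' @param labels Binary labels (0/1 or logical); both classes must occur.
#' @return A `data.frame` of class `roc_points` with columns `threshold`,
#'   `sensitivity`, `specificity`, `youden` (J = sens + spec - 1).
#' @export
roc_curve <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to build a ROC curve", call. = FALSE)

  s <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  # counts of scores >= t via cumulated class tallies over distinct scores
  k <- length(s)
  pos_at <- tabulate(match(scores, s)[labels == 1L], nbins = k)
  neg_at <- tabulate(match(scores, s)[labels == 0L], nbins = k)
  # pos_ge[i]: positives with score >= s[i]
  pos_ge <- rev(cumsum(rev(pos_at)))
  neg_ge <- rev(cumsum(rev(neg_at)))
  sens <- c(1, pos_ge[-1] / n_pos, 0)             # thresholds bracket s
  spec <- c(0, 1 - neg_ge[-1] / n_neg, 1)
  out <- data.frame(threshold = thresholds, sensitivity = sens,
                    specificity = spec, youden = sens + spec - 1)
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Youden-index optimal cutoff
#'
#' Returns the threshold maximising J = sensitivity + specificity - 1. Ties
#' are broken toward the smallest threshold and flagged.
#'
#' @param roc A [roc_curve()] result.
#' @return List with `cutoff`, `youden`, `sensitivity`, `specificity`,
#'   `tied` (logical: several thresholds attained the maximum).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_points"))
  jmax <- max(roc$youden)
  at <- which(roc$youden >= jmax - 1e-12)
  tied <- length(at) > 1L
  if (tied)
    message("youden_cutoff: ", length(at),
            " thresholds tie at J = ", signif(jmax, 4),
            "; returning the smallest")
  i <- at[1L]
  list(cutoff = roc$threshold[i], youden = roc$youden[i],
       sensitivity = roc$sensitivity[i], specificity = roc$specificity[i],
       tied = tied)
}

#' Classify nidus morphology from the compactness index
#'
#' A nidus is compact when its compactness index reaches the cutoff
#' (boundary inclusive: `ci >= cutoff`, matching the operational definition
#' "compact is compactness index >= 0.63"), otherwise diffuse.
#'
#' @param ci Positive compactness index (vectorised).
#' @param cutoff Dichotomisation cutoff (default 0.63).
#' @param boundary_compact If `FALSE`, the boundary value is called diffuse
#'   (strict `>` comparison).
#' @return Character vector in `c("compact", "diffuse")`.
#' @export
classify_morphology <- function(ci, cutoff = 0.63, boundary_compact = TRUE) {
  ci <- as.numeric(ci)
  if (any(!is.finite(ci)) || any(ci <= 0))
    stop("compactness index must be positive and finite", call. = FALSE)
  compact <- if (boundary_compact) ci >= cutoff else ci > cutoff
  ifelse(compact, "compact", "diffuse")
}
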