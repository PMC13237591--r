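#' F1-optimal decision threshold for one PT
#'
#' Scans all achievable confusion tables: candidate thresholds are the
#' midpoints between adjacent distinct sorted scores, plus sentinels just
#' below the minimum and just above the maximum score. Articles are
#' predicted positive when their score strictly exceeds the threshold.
#' When several candidates tie on F1, the largest qualifying threshold is
#' returned (favouring precision on a flat F1 plateau).
#'
#' @param scores Numeric vector of predicted probabilities.
#' @param labels Binary 0/1 vector of the same length, with at least one
#'   positive (F1 is undefined otherwise).
#' @return The selected threshold, with attributes `f1`, `precision`,
#'   `recall` at that threshold.
#' @export
select_threshold <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  if (length(scores) != length(labels) || length(scores) == 0L) {
    stop("scores and labels must be non-empty and the same length",
         call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1 and scores non-missing", call. = FALSE)
  }
  npos <- sum(labels)
  if (npos == 0L) stop("no positive labels: F1 is undefined", call. = FALSE)
  u <- sort(unique(scores))
  eps <- 1e-9
  candidates <- c(u[1L] - eps,
                  if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
                  u[length(u)] + eps)
  best_f1 <- -1
  best_t <- candidates[1L]
  best_p <- best_r <- NA_real_
  for (t in candidates) {
    pred <- scores > t
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    fn <- npos - tp
    f1 <- if (2 * tp + fp + fn == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
    # ties resolved toward the larger threshold
    if (f1 >= best_f1) {
      best_f1 <- f1
      best_t <- t
      best_p <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
      best_r <- tp / npos
    }
  }
  structure(best_t, f1 = best_f1, precision = best_p, recall = best_r)
}

#' F1-optimal thresholds for every PT column
#'
#' @param P Probability matrix (articles x PTs).
#' @param L Binary label matrix with the same dimnames.
#' @param provenance Free-text note recording which validation set the
#'   thresholds were fit on.
#' @return Named numeric vector of thresholds (one per PT), with a
#'   `provenance` attribute.
#' @export
select_thresholds <- function(P, L, provenance = "validation set") {
  validate_probability_matrix(P)
  if (!identical(dim(P), dim(L)) ||
      !identical(colnames(P), colnames(L))) {
    stop("probability and label matrices must align", call. = FALSE)
  }
  th <- vapply(colnames(P), function(pt) {
    as.numeric(select_threshold(P[, pt], L[, pt]))
  }, numeric(1L))
  attr(th, "provenance") <- provenance
  th
}

#' Threshold probabilities into binary PT tags
#'
#' A PT is tagged iff its score strictly exceeds its threshold (scores
#' exactly at the threshold are not tagged). Raising any score never
#' removes a tag.
#'
#' @param P Probability matrix (articles x PTs).
#' @param thresholds Named numeric vector covering every PT column of `P`.
#' @return Named list (one element per article) of sorted tag vectors.
#' @export
apply_thresholds <- function(P, thresholds) {
  validate_probability_matrix(P)
  missing <- setdiff(colnames(P), names(thresholds))
  if (length(missing) > 0L) {
    stop("missing threshold for PT(s): ", paste(missing, collapse = "; "),
         call. = FALSE)
  }
  th <- thresholds[colnames(P)]
  ids <- rownames(P) %||% sprintf("A%06d", seq_len(nrow(P)))
  tagged <- t(P) > th  # recycles th along PT rows
  stats::setNames(lapply(seq_len(nrow(P)), function(i) {
    sort(colnames(P)[tagged[, i]], method = "radix")
  }), ids)
}

#' Hierarchy-consistent post-prediction normalization
#'
#' Applies [normalize_tags()] per article: every assigned tag propagates
#' to all its pt-term ancestors, regardless of the ancestors' own scores.
#' Runs after thresholding, never before; never removes a tag.
#'
#' @param tags Named list of per-article tag vectors (e.g. from
#'   [apply_thresholds()]).
#' @param h A `pt_hierarchy` containing every used tag as a pt-term.
#' @return Named list of normalized per-article tag vectors.
#' @export
normalize_predictions <- function(tags, h) {
  stopifnot(inherits(h, "pt_hierarchy"))
  used <- unique(unlist(tags, use.names = FALSE))
  unknown <- setdiff(used, h$nodes$name[h$nodes$kind == "pt-term"])
  if (length(unknown) > 0L) {
    stop("tag(s) absent from the hierarchy pt-terms: ",
         paste(unknown, collapse = "; "), call. = FALSE)
  }
  lapply(tags, function(tg) normalize_tags(h, tg))
}
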