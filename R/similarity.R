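#' Pairwise Spearman similarity of PT probability columns
#'
#' The similarity between two PTs is the Spearman rank correlation of their
#' model-predicted probability columns across articles (average ranks for
#' ties). Rank correlation is used because model scores for different PTs
#' live on different, non-linearly calibrated scales; any strictly
#' increasing per-column transform leaves the result unchanged.
#'
#' A constant probability column has zero rank variance, so its correlation
#' with anything is undefined. By default this is a hard error — silently
#' propagating `NA` would corrupt downstream clustering.
#'
#' @param P Probability matrix, articles in rows, PTs in columns (at least
#'   3 articles and 2 PTs).
#' @param allow_constant If `TRUE`, constant columns yield `NA` entries
#'   instead of an error.
#' @return A symmetric similarity matrix with unit diagonal, labelled by
#'   the PT column names of `P`.
#' @export
compute_similarity <- function(P, allow_constant = FALSE) {
  validate_probability_matrix(P)
  if (nrow(P) < 3L) stop("need at least 3 articles", call. = FALSE)
  if (ncol(P) < 2L) stop("need at least 2 PT columns", call. = FALSE)
  constant <- apply(P, 2L, function(col) max(col) == min(col))
  if (any(constant) && !allow_constant) {
    stop("constant probability column(s), Spearman undefined: ",
         paste(colnames(P)[constant], collapse = "; "), call. = FALSE)
  }
  rho <- suppressWarnings(stats::cor(P, method = "spearman"))
  rho <- (rho + t(rho)) / 2
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  if (!allow_constant) validate_similarity_matrix(rho)
  rho
}

#' Enumerate all unordered PT pairs
#'
#' Every unordered pair of distinct vocabulary terms, each exactly once, in
#' deterministic lexicographic order (C collation). For the 72-term default
#' vocabulary this yields 2556 pairs.
#'
#' @param vocab Character vector of at least 2 PT names.
#' @return A data frame with columns `first` and `second`.
#' @export
enumerate_pairs <- function(vocab) {
  vocab <- pt_vocabulary(vocab)
  n <- length(vocab)
  if (n < 2L) stop("need at least 2 terms to form pairs", call. = FALSE)
  sorted <- sort(vocab, method = "radix")
  idx <- utils::combn(n, 2L)
  data.frame(first = sorted[idx[1L, ]], second = sorted[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Summary statistics and histogram of a similarity matrix
#'
#' Statistics are taken over the strict upper triangle only, so each
#' unordered PT pair is counted once. The default histogram uses 40
#' equal-width bins on \[-1, 1\], enough to resolve a near-zero mode and a
#' positive mode without over-binning.
#'
#' @param S Similarity matrix.
#' @param breaks Histogram bin edges covering \[-1, 1\].
#' @return An object of class `pt_similarity_summary`: a list with
#'   `min_offdiag`, `max_offdiag`, `mean_offdiag`, `n_pairs`, `breaks`,
#'   `counts`.
#' @export
summarize_similarity <- function(S, breaks = seq(-1, 1, length.out = 41L)) {
  validate_similarity_matrix(S)
  n <- nrow(S)
  if (n < 2L) stop("a 1x1 matrix has no pairs to summarize", call. = FALSE)
  upper <- S[upper.tri(S)]
  h <- graphics::hist(upper, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  structure(
    list(min_offdiag = min(upper),
         max_offdiag = max(upper),
         mean_offdiag = mean(upper),
         n_pairs = length(upper),
         breaks = h$breaks,
         counts = h$counts),
    class = "pt_similarity_summary")
}

#' @export
print.pt_similarity_summary <- function(x, digits = 3L, ...) {
  cat("Pairwise PT similarity summary\n")
  cat(sprintf("  pairs: %d\n", x$n_pairs))
  cat(sprintf("  min:   %.*f\n", digits, x$min_offdiag))
  cat(sprintf("  max:   %.*f\n", digits, x$max_offdiag))
  cat(sprintf("  mean:  %.*f\n", digits, x$mean_offdiag))
  invisible(x)
}
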