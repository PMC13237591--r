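#' Validate a publication-type vocabulary
#'
#' A vocabulary is an ordered character vector of publication-type and
#' study-design (PT) names. Order matters: it is preserved through every
#' downstream operation so that the order-shuffle robustness protocol is
#' meaningful.
#'
#' @param terms Character vector of PT names.
#' @return The validated character vector, invisibly unchanged.
#' @export
pt_vocabulary <- function(terms) {
  terms <- as.character(terms)
  if (length(terms) < 1L) {
    stop("a vocabulary needs at least one term", call. = FALSE)
  }
  if (anyNA(terms) || !all(nzchar(trimws(terms)))) {
    stop("vocabulary terms must be non-empty strings", call. = FALSE)
  }
  dup <- unique(terms[duplicated(terms)])
  if (length(dup) > 0L) {
    stop("duplicated vocabulary terms: ", paste(dup, collapse = "; "),
         call. = FALSE)
  }
  terms
}

#' The curated 72-term PT vocabulary
#'
#' The default vocabulary of 72 biomedical publication types and study
#' designs shipped with the package, in rubric order (the nine Scholarly
#' Publishing & Research Integrity terms last).
#'
#' @return Character vector of 72 PT names.
#' @export
ptrubric_vocabulary <- function() {
  path <- system.file("extdata", "pt_vocabulary.txt", package = "ptrubric",
                      mustWork = TRUE)
  pt_vocabulary(readLines(path, encoding = "UTF-8"))
}

#' The shipped two-level rubric
#'
#' The curated assignment of each of the 72 PTs to one of 13 low-level
#' categories and one of 5 broad categories. One PT (Scientific Integrity
#' Review) carries a manual placement flag: it is excluded from clustering
#' and placed by hand.
#'
#' @return A data frame with columns `pt`, `low_level`, `broad`, `manual`.
#' @export
ptrubric_rubric <- function() {
  path <- system.file("extdata", "pt_rubric.tsv", package = "ptrubric",
                      mustWork = TRUE)
  rub <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, encoding = "UTF-8")
  rub$manual <- as.logical(rub$manual)
  rub
}
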