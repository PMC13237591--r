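
# Delimiter inference: comma by default, tab for .tsv/.tab files or when
# explicitly requested.
infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) {
    if (!delim %in% c(",", "\t")) {
      stop("unsupported delimiter; use \",\" or \"\\t\"", call. = FALSE)
    }
    return(delim)
  }
  if (grepl("\\.(tsv|tab)$", tolower(path))) "\t" else ","
}

split_fields <- function(lines, delim) {
  strsplit(lines, delim, fixed = TRUE)
}

#' Read a per-article PT probability matrix
#'
#' Reads a delimited table whose header row holds PT names and whose first
#' column holds opaque article identifiers. Every value must lie in the
#' closed interval \[0, 1\]; rows with the wrong number of fields and
#' out-of-range cells are reported with their location.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param delim Optional explicit delimiter, `","` or `"\t"`.
#' @param vocab Optional vocabulary the columns must match exactly (same
#'   names, same order).
#' @return A numeric matrix, articles in rows (rownames are the article
#'   identifiers), PTs in columns, column order as in the file.
#' @export
read_probability_matrix <- function(path, delim = NULL, vocab = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- infer_delim(path, delim)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  fields <- split_fields(lines, delim)
  header <- fields[[1L]]
  pts <- pt_vocabulary(header[-1L])
  p <- length(pts)
  n <- length(fields) - 1L
  ids <- character(n)
  values <- matrix(NA_real_, nrow = n, ncol = p, dimnames = list(NULL, pts))
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    if (length(row) != p + 1L) {
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   i + 1L, p + 1L, length(row)), call. = FALSE)
    }
    ids[i] <- row[1L]
    values[i, ] <- suppressWarnings(as.numeric(row[-1L]))
  }
  bad <- which(is.na(values) | values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop(sprintf(
      "validation error: value %s at article '%s', PT '%s' is not in [0, 1]",
      fields[[b[1L] + 1L]][b[2L] + 1L], ids[b[1L]], pts[b[2L]]),
      call. = FALSE)
  }
  rownames(values) <- ids
  if (!is.null(vocab)) {
    if (!identical(unname(pts), unname(as.character(vocab)))) {
      stop("probability-matrix columns do not match the given vocabulary",
           call. = FALSE)
    }
  }
  validate_probability_matrix(values)
}

#' Validate a probability matrix
#'
#' @param P Numeric matrix with article rownames and PT colnames.
#' @return `P`, validated.
#' @export
validate_probability_matrix <- function(P) {
  if (!is.matrix(P) || !is.numeric(P)) {
    stop("probability matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(colnames(P))) stop("probability matrix needs PT column names",
                                 call. = FALSE)
  pt_vocabulary(colnames(P))
  if (anyNA(P)) stop("probability matrix contains missing values",
                     call. = FALSE)
  if (any(P < 0) || any(P > 1)) {
    stop("probability values must lie in [0, 1]", call. = FALSE)
  }
  P
}

#' Write a probability matrix
#'
#' Values are serialized with 6 significant digits, header row of PT names,
#' first column of article identifiers.
#'
#' @param P Probability matrix (see [read_probability_matrix()]).
#' @param path Output path; `.tsv`/`.tab` extension selects tab delimiting.
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_probability_matrix <- function(P, path, delim = NULL) {
  validate_probability_matrix(P)
  delim <- infer_delim(path, delim)
  ids <- rownames(P)
  if (is.null(ids)) ids <- sprintf("A%06d", seq_len(nrow(P)))
  header <- paste(c("article_id", colnames(P)), collapse = delim)
  body <- vapply(seq_len(nrow(P)), function(i) {
    paste(c(ids[i], format(signif(P[i, ], 6L), trim = TRUE,
                           scientific = FALSE, digits = 15L)),
          collapse = delim)
  }, character(1L))
  writeLines(c(header, body), path, useBytes = FALSE)
  invisible(path)
}

#' Read a square PT correlation matrix
#'
#' Reads a delimited square table with identical row and column labels.
#' Asymmetries up to `tol` (floating-point noise) are silently symmetrized
#' by averaging; larger asymmetries and entries outside \[-1, 1\] are
#' errors. The diagonal is set to exactly 1.
#'
#' @param path Path to the file.
#' @param delim Optional explicit delimiter.
#' @param tol Absolute asymmetry tolerance (default `1e-8`).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
read_correlation_matrix <- function(path, delim = NULL, tol = 1e-8) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- infer_delim(path, delim)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- split_fields(lines, delim)
  header <- fields[[1L]][-1L]
  n <- length(header)
  if (length(fields) - 1L != n) {
    stop(sprintf("correlation matrix is not square: %d columns, %d rows",
                 n, length(fields) - 1L), call. = FALSE)
  }
  m <- matrix(NA_real_, n, n, dimnames = list(header, header))
  row_labels <- character(n)
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    if (length(row) != n + 1L) {
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   i + 1L, n + 1L, length(row)), call. = FALSE)
    }
    row_labels[i] <- row[1L]
    m[i, ] <- suppressWarnings(as.numeric(row[-1L]))
  }
  if (!identical(row_labels, header)) {
    stop("row labels do not match column labels (same order required)",
         call. = FALSE)
  }
  if (anyNA(m)) stop("correlation matrix contains non-numeric entries",
                     call. = FALSE)
  if (any(abs(m) > 1 + tol)) {
    stop("correlation entries with |value| > 1 found", call. = FALSE)
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(sprintf("correlation matrix asymmetry %.3g exceeds tolerance %.3g",
                 asym, tol), call. = FALSE)
  }
  m <- (m + t(m)) / 2
  m[m > 1] <- 1
  m[m < -1] <- -1
  diag(m) <- 1
  validate_similarity_matrix(m)
}

#' Write a correlation/similarity matrix
#'
#' @param S Symmetric correlation matrix with labels.
#' @param path Output path; `.tsv`/`.tab` extension selects tab delimiting.
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(S, path, delim = NULL) {
  validate_similarity_matrix(S)
  delim <- infer_delim(path, delim)
  labels <- rownames(S)
  header <- paste(c("pt", labels), collapse = delim)
  body <- vapply(seq_len(nrow(S)), function(i) {
    paste(c(labels[i], format(signif(S[i, ], 6L), trim = TRUE,
                              scientific = FALSE, digits = 15L)),
          collapse = delim)
  }, character(1L))
  writeLines(c(header, body), path, useBytes = FALSE)
  invisible(path)
}

#' Validate a similarity matrix
#'
#' Checks the contract every similarity matrix in the package obeys:
#' square, labelled, symmetric within `1e-8`, unit diagonal, entries in
#' \[-1, 1\].
#'
#' @param S Matrix to validate.
#' @return `S`, validated.
#' @export
validate_similarity_matrix <- function(S) {
  if (!is.matrix(S) || !is.numeric(S) || nrow(S) != ncol(S)) {
    stop("similarity matrix must be a square numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(S)) || !identical(rownames(S), colnames(S))) {
    stop("similarity matrix needs identical row and column labels",
         call. = FALSE)
  }
  pt_vocabulary(rownames(S))
  if (anyNA(S)) stop("similarity matrix contains missing values",
                     call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(S) - 1) > 1e-8)) {
    stop("similarity matrix diagonal must be 1", call. = FALSE)
  }
  if (any(S < -1 - 1e-8) || any(S > 1 + 1e-8)) {
    stop("similarity entries must lie in [-1, 1]", call. = FALSE)
  }
  S
}
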