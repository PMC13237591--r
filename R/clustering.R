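#' Convert a similarity matrix to a distance matrix
#'
#' Correlations are inverted to dissimilarities with the standard
#' correlation distance `d = 1 - rho`, mapping \[-1, 1\] monotonically onto
#' \[0, 2\] with zero diagonal.
#'
#' @param S Similarity matrix.
#' @return A labelled distance matrix.
#' @export
to_distance <- function(S) {
  validate_similarity_matrix(S)
  d <- 1 - S
  diag(d) <- 0
  d
}

validate_distance_matrix <- function(D) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D)) {
    stop("distance matrix must be a square numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D))) {
    stop("distance matrix needs identical row and column labels",
         call. = FALSE)
  }
  if (anyNA(D)) stop("distance matrix contains missing values",
                     call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(diag(D) != 0)) stop("distance diagonal must be 0", call. = FALSE)
  if (any(D < 0)) stop("distances must be non-negative", call. = FALSE)
  D
}

#' Agglomerative Ward clustering of a precomputed distance matrix
#'
#' Builds the merge tree with the Lance--Williams "ward" update applied to
#' the distances as given (no Euclidean embedding, no squaring): merging
#' clusters i and j, the distance to any other cluster k becomes
#' \deqn{d(ij,k) = \frac{(n_i+n_k)\,d(i,k) + (n_j+n_k)\,d(j,k) -
#'   n_k\,d(i,j)}{n_i+n_j+n_k}.}
#'
#' At each step the minimum-distance active pair is merged; exact ties are
#' broken by the smallest (left-most) pair of cluster creation indices, so
#' the result is deterministic given the input order — which makes
#' order-shuffling a meaningful perturbation. Because the input distances
#' need not be Euclidean, merge heights may show inversions; they are
#' returned as computed.
#'
#' @param D Labelled symmetric distance matrix (zero diagonal).
#' @return An object of class `hclust` with components `merge`, `height`,
#'   `order` and `labels`, compatible with base plotting and with
#'   [cut_dendrogram()].
#' @export
ward_dendrogram <- function(D) {
  validate_distance_matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 labels to cluster", call. = FALSE)
  labels <- rownames(D)

  # active clusters carry: creation id (leaves -1..-n by input position,
  # merges 1..n-1), size, and a row in the working distance matrix
  d <- D
  id <- -seq_len(n)
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  # creation order key: leaves first (input order), then merge rows
  key <- function(cid) if (cid < 0L) -cid else n + cid

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- d[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    mval <- min(sub)
    cand <- which(sub == mval, arr.ind = TRUE)
    # ties: smallest creation-order pair, lexicographically
    ki <- vapply(act[cand[, 1L]], function(p) key(id[p]), numeric(1L))
    kj <- vapply(act[cand[, 2L]], function(p) key(id[p]), numeric(1L))
    lo <- pmin(ki, kj); hi <- pmax(ki, kj)
    pick <- order(lo, hi)[1L]
    i <- act[cand[pick, 1L]]
    j <- act[cand[pick, 2L]]

    a <- id[i]; b <- id[j]
    if (key(a) > key(b)) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(a, b)
    height[step] <- d[i, j]

    # Lance-Williams ward update, written into slot i
    others <- setdiff(act, c(i, j))
    if (length(others) > 0L) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      newd <- ((ni + nk) * d[i, others] + (nj + nk) * d[j, others] -
                 nk * d[i, j]) / (ni + nj + nk)
      d[i, others] <- newd
      d[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }

  structure(
    list(merge = merge, height = height, order = dendrogram_leaf_order(merge),
         labels = labels, method = "ward (Lance-Williams)",
         call = match.call(), dist.method = "precomputed"),
    class = "hclust")
}

# leaf plotting order from a merge matrix (standard recursion, iterative)
dendrogram_leaf_order <- function(merge) {
  m <- nrow(merge)
  orders <- vector("list", m)
  get <- function(x) if (x < 0L) -x else orders[[x]]
  for (i in seq_len(m)) orders[[i]] <- c(get(merge[i, 1L]), get(merge[i, 2L]))
  orders[[m]]
}

#' Cut a dendrogram into k flat clusters
#'
#' The cut undoes the last `k - 1` merges, i.e. it applies the first
#' `n - k` merges of the tree in merge order. Cutting by merge order (not
#' by height) is well defined even when Ward on a non-Euclidean distance
#' matrix produces height inversions. Cluster ids are canonical: numbered
#' 1..k by first appearance in leaf input order.
#'
#' @param dendro An `hclust`-like object (see [ward_dendrogram()]).
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A named integer vector of cluster memberships (names are the
#'   leaf labels, in input order).
#' @export
cut_dendrogram <- function(dendro, k) {
  merge <- dendro$merge
  n <- nrow(merge) + 1L
  labels <- dendro$labels
  if (length(k) != 1L || is.na(k) || k < 1L || k > n) {
    stop("k must lie between 1 and the number of leaves (", n, ")",
         call. = FALSE)
  }
  k <- as.integer(k)
  membership <- integer(n)
  members <- vector("list", n - 1L)
  consumed <- logical(n - 1L)
  leaf_consumed <- logical(n)
  steps <- n - k
  if (steps > 0L) {
    for (i in seq_len(steps)) {
      grab <- function(x) {
        if (x < 0L) { leaf_consumed[-x] <<- TRUE; -x }
        else { consumed[x] <<- TRUE; members[[x]] }
      }
      members[[i]] <- c(grab(merge[i, 1L]), grab(merge[i, 2L]))
    }
  }
  groups <- c(if (steps > 0L) members[seq_len(steps)][!consumed[seq_len(steps)]],
              as.list(which(!leaf_consumed)))
  # canonical ids by first appearance in input order
  first_leaf <- vapply(groups, min, numeric(1L))
  groups <- groups[order(first_leaf)]
  for (g in seq_along(groups)) membership[groups[[g]]] <- g
  names(membership) <- labels
  membership
}

#' Nearest-neighbour PT by similarity
#'
#' The other PT with maximal Spearman correlation to `pt`; exact ties are
#' broken lexicographically. Because selection is by label, the result is
#' invariant to the order in which PTs are stored.
#'
#' @param S Similarity matrix.
#' @param pt A PT name present in `S`.
#' @return The nearest-neighbour PT name.
#' @export
nearest_neighbour <- function(S, pt) {
  validate_similarity_matrix(S)
  if (nrow(S) < 2L) stop("need at least 2 PTs", call. = FALSE)
  if (!pt %in% rownames(S)) stop("unknown PT: ", pt, call. = FALSE)
  row <- S[pt, ]
  row <- row[names(row) != pt]
  cand <- names(row)[row == max(row)]
  sort(cand, method = "radix")[1L]
}

#' Nearest neighbours for every PT
#'
#' @param S Similarity matrix.
#' @return Named character vector: for each PT, its nearest neighbour.
#' @export
nearest_neighbours <- function(S) {
  vapply(rownames(S), function(pt) nearest_neighbour(S, pt), character(1L))
}

#' Build a two-level rubric from a distance matrix
#'
#' Clusters the PTs at two cut levels of the same Ward dendrogram. Both
#' cuts come from one tree, so every broad category is a union of
#' low-level categories by construction. PTs listed in `exclude` (by
#' default those with manual placements) are removed before clustering and
#' must carry a manual category assignment, which is merged into the
#' result and flagged.
#'
#' @param D Labelled distance matrix over the PTs.
#' @param k_low Number of low-level categories for the clustered PTs
#'   (default 13).
#' @param k_broad Number of broad categories (default 5).
#' @param manual Named list: PT name -> `c(low_level, broad)` category
#'   labels for manually placed PTs.
#' @param exclude PTs to exclude from clustering; defaults to
#'   `names(manual)`.
#' @param categories Optional character vector of known category labels;
#'   when given, manual placements naming a category outside it are an
#'   error.
#' @return A data frame with columns `pt`, `low_level`, `broad`, `manual`.
#'   Clustered categories are labelled `LL01..` and `BC1..`.
#' @export
build_rubric <- function(D, k_low = 13L, k_broad = 5L, manual = list(),
                         exclude = names(manual), categories = NULL) {
  validate_distance_matrix(D)
  if (k_broad > k_low) {
    stop("k_broad must not exceed k_low (broad categories are unions of ",
         "low-level categories)", call. = FALSE)
  }
  exclude <- as.character(exclude %||% character())
  if (length(manual) > 0L && is.null(names(manual))) {
    stop("manual placements must be a named list (PT -> categories)",
         call. = FALSE)
  }
  missing_manual <- setdiff(exclude, names(manual))
  if (length(missing_manual) > 0L) {
    stop("excluded PTs lack a manual placement: ",
         paste(missing_manual, collapse = "; "), call. = FALSE)
  }
  in_matrix <- intersect(names(manual), rownames(D))
  not_excluded <- setdiff(in_matrix, exclude)
  if (length(not_excluded) > 0L) {
    stop("manually placed PTs must be excluded from clustering or absent ",
         "from the distance matrix: ", paste(not_excluded, collapse = "; "),
         call. = FALSE)
  }
  for (pt in names(manual)) {
    cats <- as.character(manual[[pt]])
    if (length(cats) != 2L || anyNA(cats) || !all(nzchar(cats))) {
      stop("manual placement for '", pt,
           "' must give c(low_level, broad) labels", call. = FALSE)
    }
    if (!is.null(categories) && !all(cats %in% categories)) {
      stop("manual placement for '", pt, "' names an unknown category: ",
           paste(setdiff(cats, categories), collapse = "; "), call. = FALSE)
    }
  }

  keep <- setdiff(rownames(D), exclude)
  if (length(keep) < k_low) {
    stop("fewer clustered PTs than k_low", call. = FALSE)
  }
  Dc <- D[keep, keep, drop = FALSE]
  dendro <- ward_dendrogram(Dc)
  low <- cut_dendrogram(dendro, k_low)
  broad <- cut_dendrogram(dendro, k_broad)

  out <- data.frame(
    pt = keep,
    low_level = sprintf("LL%02d", low[keep]),
    broad = sprintf("BC%d", broad[keep]),
    manual = FALSE,
    stringsAsFactors = FALSE)
  if (length(manual) > 0L) {
    man <- data.frame(
      pt = names(manual),
      low_level = vapply(manual, function(x) as.character(x)[1L],
                         character(1L)),
      broad = vapply(manual, function(x) as.character(x)[2L], character(1L)),
      manual = TRUE,
      stringsAsFactors = FALSE)
    out <- rbind(out, man)
  }
  rownames(out) <- NULL
  attr(out, "dendrogram") <- dendro
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a dendrogram as Newick
#'
#' Writes a Newick rendering for tree viewers via \pkg{ape}. PT names
#' contain characters reserved in Newick (commas, parentheses, spaces);
#' they are sanitized to underscores.
#'
#' @param dendro An `hclust`-like object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dendrogram_newick <- function(dendro, path) {
  d <- dendro
  d$labels <- gsub("[ ,():;'\"\\[\\]]+", "_", d$labels)
  # as.phylo needs strictly positive-ish heights; inversions are tolerated
  phy <- ape::as.phylo(d)
  ape::write.tree(phy, file = path)
  invisible(path)
}
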