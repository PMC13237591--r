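# Independent oracles and fixture builders. These deliberately take
# different code paths from the package implementation so that each check
# is a genuine dual route.

# Spearman by definition: average-tie ranks, then Pearson on the ranks.
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  stats::cor(rx, ry)
}

# Transitive reachability by repeated squaring of the boolean adjacency
# matrix (closure in O(log n) squarings).
reachability_oracle <- function(adj) {
  n <- nrow(adj)
  reach <- adj
  repeat {
    nxt <- (reach | (reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# Exhaustive F1 scan over a dense candidate set around every score.
f1_at <- function(scores, labels, t) {
  pred <- scores > t
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}
best_f1_oracle <- function(scores, labels) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9, scores)))
  max(vapply(cand, function(t) f1_at(scores, labels, t), numeric(1)))
}

# Direct construction of a block-structured similarity matrix. Within a
# block every pair gets `within`; pass `pair_blocks = TRUE` helpers below
# for unique nearest neighbours.
make_block_similarity <- function(sizes, within = 0.9, cross = 0,
                                  names_prefix = "PT") {
  n <- sum(sizes)
  labels <- sprintf("%s%02d", names_prefix, seq_len(n))
  S <- matrix(cross, n, n, dimnames = list(labels, labels))
  start <- cumsum(c(1, sizes))[seq_along(sizes)]
  for (b in seq_along(sizes)) {
    idx <- seq(start[b], length.out = sizes[b])
    S[idx, idx] <- within
  }
  diag(S) <- 1
  list(S = S, truth = rep(seq_along(sizes), sizes), labels = labels)
}

# Pair blocks: every PT has a unique partner, so the nearest neighbour is
# uniquely determined with a large top gap.
make_pair_similarity <- function(n_pairs, within = 0.9, cross = 0) {
  make_block_similarity(rep(2L, n_pairs), within = within, cross = cross)
}

# Random valid-looking symmetric similarity matrix (not necessarily PSD;
# the matrix contract does not require it).
random_similarity <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -0.8, 0.8), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  labels <- sprintf("PT%02d", seq_len(n))
  dimnames(m) <- list(labels, labels)
  m
}

# Random distance matrix with distinct entries.
random_distance <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, 0.05, 2), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  labels <- letters[seq_len(n)]
  dimnames(m) <- list(labels, labels)
  m
}

# Random DAG over n nodes: edges only from earlier to later names in a
# fixed topological order.
random_dag <- function(n, seed, p_edge = 0.15) {
  set.seed(seed)
  names <- sprintf("N%02d", seq_len(n))
  parents <- stats::setNames(vector("list", n), names)
  adj <- matrix(FALSE, n, n, dimnames = list(names, names))
  for (i in seq_len(n)) {
    if (i == 1) { parents[[i]] <- character(); next }
    pick <- which(stats::runif(i - 1) < p_edge)
    parents[[i]] <- names[pick]
    adj[pick, i] <- TRUE  # parent -> child
  }
  kinds <- ifelse(stats::runif(n) < 0.3, "rubric-category", "pt-term")
  h <- pt_hierarchy(data.frame(name = names, kind = kinds,
                               stringsAsFactors = FALSE), parents)
  list(h = h, adj = adj, names = names)
}

# Partitions agree up to relabeling.
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
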