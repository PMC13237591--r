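#' Configuration for the perturbation stability protocol
#'
#' Defaults reproduce the full protocol: relative perturbation magnitudes
#' from 1% to 2.5% of the correlation value in increments of 0.1%, 2000
#' perturbation repetitions per magnitude, each crossed with 100
#' label-order shuffles — 200 000 combined clustering runs per magnitude.
#'
#' @param x_grid Relative perturbation magnitudes, all in (0, 1).
#' @param n_reps Perturbation repetitions per magnitude (>= 1).
#' @param n_shuffles Label-order shuffles per repetition (>= 1).
#' @param seed Integer master seed; fully determines the protocol.
#' @param k Cluster count used for the auxiliary cluster-membership
#'   retention statistic.
#' @return An object of class `pt_stability_config`.
#' @export
stability_config <- function(x_grid = seq(0.010, 0.025, by = 0.001),
                             n_reps = 2000L, n_shuffles = 100L,
                             seed = 1L, k = 13L) {
  if (any(x_grid <= 0) || any(x_grid >= 1)) {
    stop("all perturbation magnitudes must lie in (0, 1)", call. = FALSE)
  }
  if (n_reps < 1L || n_shuffles < 1L) {
    stop("n_reps and n_shuffles must be >= 1", call. = FALSE)
  }
  structure(
    list(x_grid = as.numeric(x_grid), n_reps = as.integer(n_reps),
         n_shuffles = as.integer(n_shuffles), seed = as.integer(seed),
         k = as.integer(k)),
    class = "pt_stability_config")
}

# Deterministic substream seed from a master seed and index components.
# Folds components with a Lehmer-style multiplier; all arithmetic stays
# below 2^53 so it is exact in doubles, result in [1, 2^31 - 2].
substream_seed <- function(master, ...) {
  s <- (abs(as.numeric(master)) %% 2147483562) + 1
  for (x in c(...)) {
    s <- (s * 69069 + as.numeric(x) + 1) %% 2147483562
  }
  as.integer(s + 1)
}

#' Multiplicatively perturb a similarity matrix
#'
#' Each strict-upper-triangle entry is independently multiplied by a factor
#' drawn uniformly from \{1 - x, 1, 1 + x\}, mirrored to the lower
#' triangle; the diagonal is untouched and results are clamped to
#' \[-1, 1\]. Zero correlations are fixed points of multiplicative noise.
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param S Similarity matrix.
#' @param x Relative magnitude in (0, 1).
#' @return The perturbed similarity matrix.
#' @export
perturb_similarity <- function(S, x) {
  validate_similarity_matrix(S)
  if (length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop("x must lie in (0, 1)", call. = FALSE)
  }
  up <- upper.tri(S)
  factors <- sample(c(1 - x, 1, 1 + x), sum(up), replace = TRUE)
  out <- S
  out[up] <- out[up] * factors
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out[out > 1] <- 1
  out[out < -1] <- -1
  diag(out) <- 1
  out
}

canonical_partition <- function(membership, vocab) {
  m <- membership[vocab]
  ids <- unique(m)
  as.integer(match(m, ids))
}

#' Run the perturbation + order-shuffle stability protocol
#'
#' For each magnitude `x`, each repetition draws one perturbed similarity
#' matrix ([perturb_similarity()]); each shuffle then permutes the label
#' order before Ward clustering and nearest-neighbour extraction. Results
#' are mapped back to the original label space and compared with the
#' unperturbed baseline. The per-(x, PT) statistic is the fraction of runs
#' in which the PT's nearest neighbour is unchanged; exact retention of
#' the k-cluster partition is additionally reported. The entire report is
#' bit-reproducible given the config seed.
#'
#' @param S Similarity matrix.
#' @param cfg A [stability_config()].
#' @return An object of class `pt_stability_report`: list with `x_grid`,
#'   `retention` (magnitude x PT matrix of fractions), `min_retention`
#'   (per magnitude), `partition_retention` (per magnitude),
#'   `runs_per_x`, `n_runs` (the executed-run counter), `config`.
#' @export
run_stability <- function(S, cfg = stability_config()) {
  validate_similarity_matrix(S)
  stopifnot(inherits(cfg, "pt_stability_config"))
  vocab <- rownames(S)
  n <- length(vocab)
  k <- min(cfg$k, n)

  base_nn <- nearest_neighbours(S)
  base_part <- canonical_partition(
    cut_dendrogram(ward_dendrogram(to_distance(S)), k), vocab)

  nx <- length(cfg$x_grid)
  retention <- matrix(0, nx, n, dimnames = list(
    format(cfg$x_grid, trim = TRUE), vocab))
  part_ret <- numeric(nx)
  n_runs <- 0L

  for (ix in seq_len(nx)) {
    x <- cfg$x_grid[ix]
    nn_hits <- stats::setNames(numeric(n), vocab)
    part_hits <- 0L
    for (r in seq_len(cfg$n_reps)) {
      set.seed(substream_seed(cfg$seed, ix, r, 0L))
      Sp <- perturb_similarity(S, x)
      Dp <- to_distance(Sp)
      for (s in seq_len(cfg$n_shuffles)) {
        set.seed(substream_seed(cfg$seed, ix, r, s))
        perm <- sample.int(n)
        Dps <- Dp[perm, perm, drop = FALSE]
        part <- canonical_partition(
          cut_dendrogram(ward_dendrogram(Dps), k), vocab)
        nn <- nearest_neighbours(Sp[perm, perm, drop = FALSE])
        n_runs <- n_runs + 1L
        nn_hits <- nn_hits + (nn[vocab] == base_nn)
        part_hits <- part_hits + identical(part, base_part)
      }
    }
    runs <- cfg$n_reps * cfg$n_shuffles
    retention[ix, ] <- nn_hits / runs
    part_ret[ix] <- part_hits / runs
  }

  structure(
    list(x_grid = cfg$x_grid, retention = retention,
         min_retention = apply(retention, 1L, min),
         partition_retention = part_ret,
         runs_per_x = cfg$n_reps * cfg$n_shuffles,
         n_runs = n_runs, config = cfg),
    class = "pt_stability_report")
}

#' @export
print.pt_stability_report <- function(x, ...) {
  cat("PT nearest-neighbour stability report\n")
  cat(sprintf("  magnitudes: %s\n",
              paste(format(range(x$x_grid)), collapse = " .. ")))
  cat(sprintf("  runs per magnitude: %d (executed total: %d)\n",
              x$runs_per_x, x$n_runs))
  cat(sprintf("  min retention over PTs: %s\n",
              paste(format(round(range(x$min_retention), 4)),
                    collapse = " .. ")))
  invisible(x)
}

#' Check clustering invariance under label-order shuffles
#'
#' Clusters the matrix under `n_shuffles` random label permutations, maps
#' each partition back to the original label space and compares with the
#' unshuffled partition. Passes iff all partitions are identical; when
#' merge ties make the result order-dependent, the discordant permutations
#' are reported.
#'
#' @param S Similarity matrix.
#' @param k Cluster count.
#' @param n_shuffles Number of random permutations.
#' @param seed Integer seed.
#' @return List with `pass`, `n_checked`, `discordant` (list of
#'   permutations yielding a different partition).
#' @export
shuffle_invariance_check <- function(S, k, n_shuffles = 100L, seed = 1L) {
  validate_similarity_matrix(S)
  vocab <- rownames(S)
  n <- length(vocab)
  D <- to_distance(S)
  base <- canonical_partition(cut_dendrogram(ward_dendrogram(D), k), vocab)
  discordant <- list()
  for (s in seq_len(n_shuffles)) {
    set.seed(substream_seed(seed, s))
    perm <- sample.int(n)
    part <- canonical_partition(
      cut_dendrogram(ward_dendrogram(D[perm, perm, drop = FALSE]), k), vocab)
    if (!identical(part, base)) discordant[[length(discordant) + 1L]] <- perm
  }
  list(pass = length(discordant) == 0L, n_checked = as.integer(n_shuffles),
       discordant = discordant)
}
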