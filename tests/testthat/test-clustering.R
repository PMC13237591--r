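test_that("correlation-to-distance conversion is 1 - rho with zero diagonal", {
  S <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(to_distance(S)["A", "B"], 0)
  S[1, 2] <- S[2, 1] <- -1
  expect_equal(to_distance(S)["A", "B"], 2)
  S[1, 2] <- S[2, 1] <- 0.176
  expect_equal(to_distance(S)["A", "B"], 0.824)
  expect_equal(diag(to_distance(S)), c(A = 0, B = 0))
})

test_that("two leaves merge once at their pairwise distance", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  hc <- ward_dendrogram(D)
  expect_equal(nrow(hc$merge), 1L)
  expect_equal(hc$height, 0.4)
  expect_setequal(hc$merge[1, ], c(-1L, -2L))
})

test_that("well-separated planted pairs merge within pairs before across", {
  # two tight pairs far apart: within distance 0.1, across 1.5
  D <- matrix(1.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D[1, 2] <- D[2, 1] <- 0.1
  D[3, 4] <- D[4, 3] <- 0.12
  diag(D) <- 0
  hc <- ward_dendrogram(D)
  expect_setequal(hc$merge[1, ], c(-1L, -2L))
  expect_setequal(hc$merge[2, ], c(-3L, -4L))
  expect_setequal(hc$merge[3, ], c(1L, 2L))
})

test_that("Ward merge heights and partitions match stats::hclust ward.D", {
  for (seed in 1:12) {
    n <- 5 + seed %% 4
    D <- random_distance(n, seed)
    mine <- ward_dendrogram(D)
    ref <- stats::hclust(stats::as.dist(D), method = "ward.D")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-10)
    for (k in 2:(n - 1)) {
      a <- cut_dendrogram(mine, k)
      b <- stats::cutree(ref, k)[names(a)]
      expect_true(same_partition(a, b))
    }
  }
})

test_that("dendrogram cuts are exhaustive, nested and bounded", {
  D <- random_distance(9, seed = 21)
  hc <- ward_dendrogram(D)
  expect_equal(unname(cut_dendrogram(hc, 1)), rep(1L, 9))
  expect_equal(unname(cut_dendrogram(hc, 9)), 1:9)
  expect_error(cut_dendrogram(hc, 0), "between 1")
  expect_error(cut_dendrogram(hc, 10), "between 1")
  # nesting: every k2-cluster sits inside exactly one k1-cluster (k1 < k2)
  for (k1 in 2:4) for (k2 in (k1 + 1):8) {
    coarse <- cut_dendrogram(hc, k1)
    fine <- cut_dendrogram(hc, k2)
    expect_equal(length(unique(paste(fine, coarse))), k2)
  }
})

test_that("cutting at k recovers planted blocks exactly", {
  blocks <- make_block_similarity(rep(4L, 13), within = 0.9, cross = 0)
  part <- cut_dendrogram(ward_dendrogram(to_distance(blocks$S)), 13)
  expect_true(same_partition(part, blocks$truth))
  expect_equal(mclust::adjustedRandIndex(part, blocks$truth), 1)
})

test_that("relabeling the input yields the same partition up to renaming", {
  S <- random_similarity(10, seed = 5)
  D <- to_distance(S)
  base <- cut_dendrogram(ward_dendrogram(D), 4)
  for (seed in 1:5) {
    set.seed(seed)
    perm <- sample(10)
    part <- cut_dendrogram(ward_dendrogram(D[perm, perm]), 4)
    expect_true(same_partition(part[rownames(D)], base))
  }
})

test_that("nearest neighbour maximizes similarity with lexicographic ties", {
  S2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(nearest_neighbour(S2, "A"), "B")
  expect_equal(nearest_neighbour(S2, "B"), "A")

  S <- random_similarity(10, seed = 9)
  for (pt in rownames(S)) {
    row <- S[pt, ]
    row[pt] <- -Inf
    expect_equal(nearest_neighbour(S, pt), names(which.max(row)))
  }
  expect_error(nearest_neighbour(S, "nope"), "unknown PT")

  # engineered tie resolves to the lexicographically smaller label
  St <- matrix(0.2, 3, 3, dimnames = list(c("B", "C", "A"), c("B", "C", "A")))
  St["B", "C"] <- St["C", "B"] <- 0.8
  St["B", "A"] <- St["A", "B"] <- 0.8
  diag(St) <- 1
  expect_equal(nearest_neighbour(St, "B"), "A")
})

test_that("rubric cuts nest and manual placements are merged in and flagged", {
  # 4 planted blocks grouped in 2 super-blocks
  n <- 16
  labels <- sprintf("PT%02d", 1:n)
  S <- matrix(0, n, n, dimnames = list(labels, labels))
  blocks <- list(1:4, 5:8, 9:12, 13:16)
  for (b in blocks) S[b, b] <- 0.9
  S[1:8, 1:8][S[1:8, 1:8] == 0] <- 0.4     # super-block 1
  S[9:16, 9:16][S[9:16, 9:16] == 0] <- 0.4 # super-block 2
  diag(S) <- 1
  D <- to_distance(S)
  rub <- build_rubric(D, k_low = 4, k_broad = 2)
  truth_low <- rep(1:4, each = 4)
  truth_broad <- rep(1:2, each = 8)
  expect_true(same_partition(rub$low_level, truth_low))
  expect_true(same_partition(rub$broad, truth_broad))
  # broad categories are unions of low-level categories
  expect_equal(length(unique(paste(rub$low_level, rub$broad))), 4L)

  # manual placement: excluded from clustering, flagged in the result
  manual <- list("PT16" = c("Hand-Placed", "Hand-Placed Broad"))
  rub2 <- build_rubric(D, k_low = 4, k_broad = 2, manual = manual)
  expect_equal(nrow(rub2), n)
  row16 <- rub2[rub2$pt == "PT16", ]
  expect_true(row16$manual)
  expect_equal(row16$low_level, "Hand-Placed")
  expect_false(any(rub2$manual[rub2$pt != "PT16"]))

  # k_low = k_broad collapses the two levels to the same partition
  rub3 <- build_rubric(D, k_low = 4, k_broad = 4)
  expect_true(same_partition(rub3$low_level, rub3$broad))
})

test_that("rubric rejects inconsistent manual placement requests", {
  S <- random_similarity(6, seed = 2)
  D <- to_distance(S)
  # manual PT still in the matrix and not excluded
  expect_error(
    build_rubric(D, k_low = 2, k_broad = 2,
                 manual = list(PT01 = c("X", "Y")), exclude = character()),
    "excluded")
  # excluded PT without a manual category
  expect_error(
    build_rubric(D, k_low = 2, k_broad = 2, exclude = "PT01"),
    "lack a manual placement")
  # manual category outside the known roster
  expect_error(
    build_rubric(D, k_low = 2, k_broad = 2,
                 manual = list(PT01 = c("Unknown", "AlsoUnknown")),
                 categories = c("Known", "KnownBroad")),
    "unknown category")
})

test_that("newick export writes a tree with all sanitized labels", {
  D <- random_distance(6, seed = 3)
  dimnames(D) <- list(paste("Clinical Trial, Phase", 1:6),
                      paste("Clinical Trial, Phase", 1:6))
  hc <- ward_dendrogram(D)
  f <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_newick(hc, f)
  txt <- readLines(f)
  expect_match(txt, "^\\(")
  expect_equal(lengths(regmatches(txt, gregexpr("Clinical_Trial", txt))), 6L)
})
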