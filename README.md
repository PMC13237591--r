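# ptrubric

Data-driven organization of biomedical publication types and study
designs (PTs), for people who build or evaluate automated literature
indexing: a similarity metric over model-predicted PT probabilities, a
clustered two-level rubric, a perturbation-based stability protocol, and
a unified PT hierarchy for query expansion and post-prediction tag
normalization.

## What it computes

Modern indexers assign each article a probability $P \in (0,1)$ for each
of 72 PTs. For PT columns $p_i, p_j$ over $N$ articles, `ptrubric`
computes the Spearman rank correlation $\rho_{ij}$ (average-rank ties)
for all $n(n-1)/2 = 2556$ unordered pairs, forming a 72 × 72 similarity
matrix. Correlations are inverted to distances $d = 1-\rho$ and
clustered agglomeratively under the Ward criterion (Lance–Williams
update on the distances as given, deterministic tie-breaking); cutting
the tree at 13 and at 5 clusters yields the low-level and broad rubric
categories. Robustness is established by multiplying each correlation by
a factor from $\{1-x, 1, 1+x\}$ for $x$ from 1% to 2.5% (step 0.1%),
2000 repetitions per magnitude crossed with 100 PT-order shuffles
(200 000 runs per magnitude), and measuring the fraction of runs in
which each PT's nearest neighbour is unchanged.

The package also ships a curated 72-term vocabulary, the 13/5-category
rubric, and a unified PT hierarchy in computable JSON with
`expand_query()` (a term plus everything below it) and
`normalize_tags()` (add all pt-term ancestors of each assigned tag), plus
per-PT F1-optimal threshold selection and a Gaussian-copula synthetic
generator with planted block structure for end-to-end testing.

## Worked example

Synthetic probabilities with the 72-term vocabulary planted in 13
rubric-sized correlation blocks, through the full pipeline:

```r
library(ptrubric)

cfg <- fig2like_scenario(seed = 42, n_articles = 2000)
sim <- generate_probabilities(cfg)
S   <- compute_similarity(sim$probabilities)
summarize_similarity(S)
#> Pairwise PT similarity summary
#>   pairs: 2556
#>   min:   -0.262
#>   max:   0.638
#>   mean:  0.041

nearest_neighbour(S, "Case Series")
#> [1] "Case Reports"

rub <- build_rubric(to_distance(S), k_low = 13, k_broad = 5)
length(unique(rub$low_level)); length(unique(rub$broad))
#> [1] 13
#> [1] 5
mclust::adjustedRandIndex(rub$low_level, sim$truth$membership[rub$pt])
#> [1] 1

normalize_tags(ptrubric_hierarchy(), "Cohort Studies")
#> [1] "Clinical Study"      "Cohort Studies"      "Observational Study"
```

The 2556 pairs split into a dominant near-zero mode (cross-block pairs)
and a positive mode near the planted within-block correlation of 0.6;
the negative tail comes from the two negatively coupled block pairs.
Cutting the Ward tree at 13 recovers the planted blocks exactly
(adjusted Rand index 1), and tag normalization closes each tag set
upward through the hierarchy.

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "ptrubric.R", package = "ptrubric")` with
subcommands `simulate`, `similarity`, `cluster`, `stability`,
`hierarchy-*`, `thresholds`, `predict` and `run`.

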