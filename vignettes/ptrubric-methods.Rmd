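---
title: "Organizing publication types: similarity, rubric, stability and hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organizing publication types: similarity, rubric, stability and hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biomedical articles are indexed with publication types and study-design
terms (collectively, PTs): Randomized Controlled Trial, Cohort Studies,
Case Reports, Editorial, and so on. In the MeSH controlled vocabulary
these terms are scattered across several hierarchy trees, and tree
proximity is a poor proxy for how similar two PTs actually are. Modern
automated indexers emit, for every article, a probability that each PT
applies. Those per-article probability vectors carry an empirical signal:
PTs that tend to score high on the same articles are functionally
related, whether or not MeSH places them near each other.

`ptrubric` turns that signal into three artifacts:

1. a **similarity matrix** — pairwise Spearman correlations between PT
   probability columns;
2. a **rubric** — a two-level flat grouping (13 low-level, 5 broad
   categories over 72 PTs) obtained by Ward clustering of the
   correlation-derived distances, with a perturbation protocol that
   checks the grouping is not an artifact of noise or list order;
3. a **unified hierarchy** — a single parent/child arrangement of all 72
   PT terms plus rubric categories, serialized as JSON, supporting
   PubMed-style query expansion and post-prediction tag normalization.

## The similarity metric

For probability columns $p_i, p_j \in (0,1)^N$ over $N$ articles, the
similarity is the Spearman rank correlation $\rho_{ij}$ (average ranks
for ties, the standard midrank convention). Rank correlation is the right
invariance class here: per-PT score calibrations are arbitrary monotone
transforms, and $\rho$ is invariant to any strictly increasing
per-column transform. Ties are essentially absent in real model scores,
so the midrank choice is inert in practice; it matters only for
degenerate inputs. A constant column has zero rank variance and no
defined correlation — `compute_similarity()` treats it as a hard error
rather than propagating `NA` into the clustering (an explicit
`allow_constant` flag restores the permissive behaviour for exploratory
use).

Summary statistics (`summarize_similarity()`) are taken over the strict
upper triangle, so each of the $n(n-1)/2$ unordered pairs counts once
(2556 pairs for 72 PTs). The default histogram uses 40 equal-width bins
on $[-1, 1]$: wide enough to resolve a near-zero mode and a positive
mode separately, narrow enough not to fragment them.

## Distances and Ward clustering

Correlations are inverted to dissimilarities with the standard
correlation distance $d = 1 - \rho$, mapping $[-1,1]$ monotonically onto
$[0,2]$. The merge tree is built agglomeratively under the Ward
criterion, applied to the precomputed distances as given through the
Lance–Williams recurrence

$$d(ij,k) = \frac{(n_i+n_k)\,d(i,k) + (n_j+n_k)\,d(j,k) - n_k\,d(i,j)}
{n_i+n_j+n_k}.$$

Two numerical conventions deserve to be explicit, because the input
distances are not Euclidean:

* **No embedding, no squaring.** The recurrence is applied to $1-\rho$
  directly (the `ward.D` convention), not to squared Euclidean
  coordinates. Merge heights can therefore show inversions; the package
  neither asserts nor repairs monotone heights.
* **Deterministic tie-breaking.** When two candidate merges are exactly
  tied, the pair with the smallest (left-most) cluster creation indices
  is merged. This makes the algorithm a deterministic function of the
  input order — which is precisely what makes *shuffling* the input
  order a meaningful perturbation: any order-dependence that survives is
  a genuine tie in the data, and `shuffle_invariance_check()` reports
  the discordant permutations instead of hiding them.

The implementation is authored in the package (the tie rule and
merge-order cutting are load-bearing); `stats::hclust(method = "ward.D")`
serves as an independent cross-check in the test suite, where merge
heights and all flat cuts agree on random tie-free inputs.

**Cutting.** `cut_dendrogram(d, k)` undoes the last $k-1$ merges, i.e.
cuts by merge order rather than by height. On inputs with height
inversions the two notions differ, and merge-order cutting is the one
that is always well defined. Both rubric levels (defaults $k_{low}=13$,
$k_{broad}=5$) are cut from the *same* tree, so broad categories are
unions of low-level categories by construction. PTs excluded from
clustering (in the shipped rubric: Scientific Integrity Review, too
rarely tagged to carry a reliable probability column) must be given a
manual category, which is merged in and flagged.

## The stability protocol

The protocol asks: does the identification of each PT's
nearest-neighbour PT survive small distortions of the correlations and
reordering of the input?

* Each strict-upper-triangle entry is independently multiplied by a
  factor drawn uniformly from $\{1-x,\ 1,\ 1+x\}$, for relative
  magnitudes $x$ from 1% to 2.5% in steps of 0.1% (16 values). Noise is
  applied in correlation space (the quantity of interest), mirrored for
  symmetry, clamped to $[-1,1]$; zero correlations are fixed points of
  multiplicative noise.
* For each magnitude, 2000 perturbation repetitions are each crossed
  with 100 label-order shuffles: 200 000 combined clustering runs per
  magnitude. The report carries an executed-run counter alongside the
  accounting formula $n_{reps} \times n_{shuffles}$, so the bookkeeping
  is verifiable at reduced scale (the tests use 20 × 10).
* Per (magnitude, PT), the statistic is the fraction of runs in which
  the nearest neighbour equals the unperturbed one, compared in the
  original label space. Exact retention of the $k$-cluster partition is
  reported as an auxiliary statistic but is not the stability criterion.

Randomness flows from one master seed through deterministic per-(x,
repetition, shuffle) substreams, so the full report is bit-reproducible
and runs are order-independent by contract.

A point worth understanding before interpreting retention values:
**retention 1.0 requires a unique nearest neighbour with a top-gap
exceeding the perturbation range.** If a PT's two highest correlations
are exactly tied (as happens in idealized block matrices with constant
within-block correlation), any perturbation breaks the tie at random and
retention hovers near $1/m$ for $m$ tied partners — not because the
clustering is fragile but because the question "which single neighbour?"
has no unique answer. The package's stability tests therefore use
well-separated synthetic structures with uniquely determined neighbours
(pair blocks: within-pair correlation 0.9 against a background of 0, so
the top gap dwarfs the ±2.5% noise); on those, retention is 1.0 across
the entire default grid, and mean retention is non-increasing in $x$
when competitors are engineered close together.

## The synthetic generator

Real model scores are not redistributable, so every pipeline stage is
exercised on synthetic probability matrices with *planted, known*
structure. The generator is a Gaussian copula: article latent vectors
are drawn from a correlated normal via the symmetric eigen square root
of the target matrix, then pushed through a logistic sigmoid shifted to
each PT's base rate. Because the sigmoid is monotone, ranks — and hence
the Spearman structure — are inherited from the copula exactly.

Two design choices matter:

* **Targets are Spearman targets.** For a Gaussian copula the Spearman
  correlation of the outputs is $(6/\pi)\arcsin(r/2)$ for latent Pearson
  $r$, so the generator pre-warps each target through
  $r = 2\sin(\pi\rho_s/6)$. Stated block targets are met on the scale
  the pipeline actually measures.
* **Non-PSD targets are refused, not repaired.** A silently "fixed"
  target matrix would change the planted truth the tests rely on; the
  error reports the offending eigenvalue instead.

The canned `fig2like_scenario()` partitions the 72-term vocabulary into
13 blocks sized like the shipped rubric's low-level categories, with
within-block Spearman target 0.6, cross-block 0, and two negatively
correlated block pairs (narrative/commentary material against clinical
blocks, −0.2), at 5000 articles. The 0.6 within-block level and the −0.2
negative couplings are stand-in choices of realistic magnitude, not
measured values; the block sizes are the rubric's. Its pooled
off-diagonal correlation distribution is bimodal — a dominant near-zero
mode from the ~2350 cross-block pairs and a secondary mode near 0.6 from
the 200 within-block pairs — and the full pipeline (similarity →
distance → Ward → cut at 13) recovers the planted partition with
adjusted Rand index ≥ 0.95 at that sample size (1.0 in practice).

What the generator does *not* emulate: article text and metadata,
label sparsity and class imbalance, NLM's most-specific-term-only
indexing behaviour, or the long-tailed dependence structure of real
score distributions. Passing tests demonstrate that the pipeline
recovers structure that is truly present at realistic noise levels; they
do not certify any particular published correlation value, which
requires the published matrix itself.

## The unified hierarchy

The hierarchy is a validated DAG (`pt_hierarchy`): unique node names,
resolvable parent links, acyclicity checked by Kahn's algorithm with the
offending cycle named, at least one root. Multiple parents are supported
— MeSH is polyhierarchical and protocol articles arguably belong under
both a protocol term and a trials-as-topic term — although the shipped
fixture is a tree.

The shipped fixture encodes a curated arrangement of all 72 PT terms
plus 11 rubric-category nodes, with 5 roots: three broad categories
(Clinical Evaluation & Validation; Qualitative & Genetic Methods;
Scholarly Discourse and Evidence Synthesis) and two top-level PT terms
(Multicentre Study; Clinical Study). The interventional and
observational material sits *under* Clinical Study rather than under
separate category roots: Clinical Trial carries the trial subtypes,
phases, protocol and allocation-methodology terms as direct children;
Observational Study carries the epidemiologic designs plus Case
Reports/Case Series; Retrospective and Prospective Studies attach
directly to Clinical Study, since those designs can be either
observational or interventional. The rubric's flat categories and the
hierarchy's placement are deliberately independent annotations — the
clustering groups terms by how indexers actually use them, the hierarchy
by logical subsumption, and the two legitimately disagree (NLM indexers
attach only the most specific applicable term, so "Clinical Study" in
practice marks articles that are *not* trials even though trials are
logically clinical studies).

Operations on the DAG: `descendants()`/`ancestors()` are transitive
closures (BFS; cross-checked against boolean-matrix reachability in the
tests); `expand_query(term)` returns the term plus its pt-term
descendants (what PubMed's automatic expansion does for MeSH queries);
`normalize_tags(tags)` adds every pt-term ancestor of each tag. Both are
monotone and idempotent. Rubric-category nodes are excluded from both
outputs by default — categories organize the vocabulary, they are not
indexing targets — with an `include_categories` flag for the other view.

## Thresholding and post-prediction normalization

`select_threshold()` picks the per-PT decision threshold maximizing F1
over a finite, complete candidate set: midpoints between adjacent
distinct sorted scores plus sentinels below the minimum and above the
maximum — every achievable confusion table is visited exactly once. The
tagging convention is a strict inequality (score must *exceed* the
threshold), and F1 ties resolve to the largest qualifying threshold,
favouring precision on a flat plateau. Thresholds are fit on raw scores
only; `normalize_predictions()` then closes each article's tag set under
pt-term ancestors, after thresholding and never before, so an article
tagged Cohort Studies is also tagged Observational Study and Clinical
Study regardless of those terms' own scores. Normalization only adds
tags; hierarchy consistency (every tagged PT has all its pt-term
ancestors tagged) holds exactly afterwards.

## Degenerate inputs and numerical conventions

* Correlation input: asymmetries up to `1e-8` are averaged away
  (floating-point noise from serialization); larger asymmetries are data
  errors and refused. Entries beyond $[-1,1]$ by more than the tolerance
  are refused; the diagonal is forced to exactly 1.
* Matrix serialization: delimited text (comma default, tab accepted),
  6 significant digits — human-diffable, and round-trips to well under
  `1e-6` absolute error.
* Fully tied matrices (all off-diagonal values equal) cluster without
  crashing; the shuffle check then reports the order-dependence instead
  of pretending determinism.
* Nearest-neighbour ties break lexicographically, making the result
  label-order invariant.
* Substream seeds are folded with multiply-mod arithmetic kept below
  $2^{53}$, so seed derivation is exact in doubles and identical across
  platforms.

## Problem sizes used in the tests

The shipped test suite and acceptance script run the protocol at sizes
chosen to exercise every code path while keeping a laptop run in
seconds: planted-partition recovery at 5000 articles × 72 PTs (the full
vocabulary), stability at 16-point default grids with 25 × 4 and 20 × 10
rep/shuffle counts on 6–8 PT matrices, and oracle comparisons on 5–8
point inputs where exhaustive enumeration is feasible. The full
2000 × 100 protocol on a 72 × 72 matrix is a configuration change, not a
code change (`stability_config()` defaults), and takes on the order of
minutes per magnitude on one CPU.

## Known limitations

* The published 72×72 correlation matrix is not redistributable with the
  package; checks that require it look for
  `inst/extdata/pt_spearman_supplementary.csv` and fail informatively
  when it is absent. All other checks are self-contained.
* Ward on non-Euclidean correlation distances is a convention, not a
  theorem; other linkage conventions (squared distances, `ward.D2`)
  yield different trees, and no claim is made that the convention here
  is uniquely correct — only that it is standard, deterministic and
  documented.
* The rubric's category *labels* are curated, not discovered; clustering
  fixes the partition, naming is editorial.
* Automatic selection of the number of clusters is out of scope; the
  cut sizes are inputs.
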