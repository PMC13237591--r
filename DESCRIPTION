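Package: ptrubric
Title: Similarity Metric, Rubric and Unified Hierarchy for Biomedical
    Publication Types and Study Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Organizes biomedical publication types and study designs (PTs)
    in a data-driven way. Computes a pairwise Spearman similarity matrix
    from model-predicted per-article PT probabilities, converts it to
    distances and clusters PTs with Ward linkage into a two-level rubric
    (low-level and broad categories), and assesses clustering robustness
    under multiplicative perturbation of the correlations and shuffling of
    the PT order. Ships a curated 72-term PT vocabulary, a 13/5-category
    rubric and a unified PT hierarchy in computable JSON, with
    descendant-based query expansion and post-prediction tag normalization,
    plus per-PT F1-optimal threshold selection and a Gaussian-copula
    synthetic generator with planted block-correlation structure for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
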