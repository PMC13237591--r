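fixture_h <- ptrubric_hierarchy()
fixture_v <- ptrubric_vocabulary()

test_that("single-node hierarchies load and are their own root", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes":[{"name":"Solo","kind":"pt-term","parents":[]}]}', f)
  h <- load_hierarchy(f)
  expect_equal(hierarchy_roots(h), "Solo")
  expect_equal(descendants(h, "Solo"), character())
})

test_that("cycles and dangling parents are rejected by name", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"nodes":[',
                    '{"name":"A","kind":"pt-term","parents":["B"]},',
                    '{"name":"B","kind":"pt-term","parents":["A"]}]}'), f)
  expect_error(load_hierarchy(f), "cycle")
  writeLines(paste0('{"nodes":[',
                    '{"name":"A","kind":"pt-term","parents":["Ghost"]}]}'), f)
  expect_error(load_hierarchy(f), "dangling.*A.*Ghost")
})

test_that("the shipped fixture has 5 roots and exactly the 72-term vocabulary", {
  expect_length(hierarchy_roots(fixture_h), 5L)
  rep <- validate_hierarchy(fixture_h, fixture_v)
  expect_true(rep$ok)
  expect_length(rep$missing_in_hierarchy, 0L)
  expect_length(rep$missing_in_vocab, 0L)
  expect_setequal(
    c("Clinical Evaluation & Validation", "Multicentre Study",
      "Clinical Study", "Qualitative & Genetic Methods",
      "Scholarly Discourse and Evidence Synthesis"),
    rep$roots)
})

test_that("Clinical Study spans trials, protocols and observational designs", {
  desc <- descendants(fixture_h, "Clinical Study")
  expect_true(all(c("Clinical Trial", "Clinical Trial Protocol",
                    "Observational Study", "Retrospective Studies",
                    "Prospective Studies") %in% desc))
  exp <- expand_query(fixture_h, "Observational Study")
  expect_true(all(c("Observational Study", "Case-Control Studies",
                    "Cross-Sectional Studies", "Longitudinal Studies",
                    "Cohort Studies", "Follow-Up Studies", "Case Reports",
                    "Case Series") %in% exp))
  # leaves expand to themselves
  expect_equal(expand_query(fixture_h, "Twin Study"), "Twin Study")
})

test_that("normalization adds pt-term ancestors and is a closure", {
  norm <- normalize_tags(fixture_h, "Cohort Studies")
  expect_setequal(norm, c("Cohort Studies", "Observational Study",
                          "Clinical Study"))
  expect_equal(normalize_tags(fixture_h, character()), character())
  expect_equal(normalize_tags(fixture_h, norm), norm)  # fixed point
  expect_error(normalize_tags(fixture_h, "Nonexistent"), "unknown tag")
})

test_that("closure operations match repeated-squaring reachability on random DAGs", {
  for (seed in 1:8) {
    dag <- random_dag(20, seed)
    reach <- reachability_oracle(dag$adj)
    for (nm in dag$names) {
      expect_setequal(descendants(dag$h, nm), dag$names[reach[nm, ]])
      expect_setequal(ancestors(dag$h, nm), dag$names[reach[, nm]])
    }
    # mutual consistency: a in ancestors(b) iff b in descendants(a)
    a <- dag$names[3]; b <- dag$names[17]
    expect_equal(a %in% ancestors(dag$h, b), b %in% descendants(dag$h, a))
  }
})

test_that("expansion and normalization are idempotent and monotone", {
  for (term in c("Clinical Study", "Clinical Trial", "Evidence Synthesis & Clinical Guidance")) {
    once <- expand_query(fixture_h, term, include_categories = TRUE)
    again <- sort(unique(unlist(
      lapply(once, expand_query, h = fixture_h, include_categories = TRUE))),
      method = "radix")
    expect_equal(again, once)  # idempotent closure
  }
  set.seed(31)
  ptterms <- fixture_h$nodes$name[fixture_h$nodes$kind == "pt-term"]
  for (i in 1:10) {
    small <- sample(ptterms, 3)
    big <- unique(c(small, sample(ptterms, 4)))
    ns <- normalize_tags(fixture_h, small)
    nb <- normalize_tags(fixture_h, big)
    expect_true(all(ns %in% nb))               # monotone
    expect_equal(normalize_tags(fixture_h, ns), ns)  # idempotent
    expect_true(all(small %in% ns))            # never removes a tag
  }
})

test_that("every parent expansion contains its child expansions in the fixture", {
  for (nm in fixture_h$nodes$name) {
    for (ch in fixture_h$children[[nm]]) {
      expect_true(all(expand_query(fixture_h, ch, include_categories = TRUE)
                      %in% expand_query(fixture_h, nm,
                                        include_categories = TRUE)))
    }
  }
})

test_that("validation reports vocabulary mismatches and orphaned categories", {
  rep <- validate_hierarchy(fixture_h, c(fixture_v, "Invented Term"))
  expect_equal(rep$missing_in_hierarchy, "Invented Term")
  expect_false(rep$ok)

  nodes <- data.frame(name = c("Root", "Empty Cat"),
                      kind = c("pt-term", "rubric-category"),
                      stringsAsFactors = FALSE)
  h <- pt_hierarchy(nodes, list(Root = character(),
                                `Empty Cat` = character()))
  rep2 <- validate_hierarchy(h, "Root")
  expect_equal(rep2$empty_categories, "Empty Cat")
})

test_that("save then load is the identity", {
  f <- withr::local_tempfile(fileext = ".json")
  save_hierarchy(fixture_h, f)
  back <- load_hierarchy(f)
  expect_identical(back$nodes, fixture_h$nodes)
  expect_identical(back$parents, fixture_h$parents)
  # polyhierarchy survives the round trip
  dag <- random_dag(12, seed = 9, p_edge = 0.3)
  save_hierarchy(dag$h, f)
  expect_identical(load_hierarchy(f)$parents, dag$h$parents)
})
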