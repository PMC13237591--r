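#' Build a validated PT hierarchy
#'
#' The unified hierarchy is a DAG over PT terms and rubric categories.
#' Nodes are `pt-term` (indexing targets, MeSH-style) or `rubric-category`
#' (organizational). Multiple parents are allowed (polyhierarchy, as in
#' MeSH), although the shipped fixture is a tree.
#'
#' @param nodes A data frame with columns `name` and `kind`.
#' @param parents Named list: node name -> character vector of parent
#'   names (empty for roots).
#' @return An object of class `pt_hierarchy`.
#' @export
pt_hierarchy <- function(nodes, parents) {
  if (!all(c("name", "kind") %in% names(nodes))) {
    stop("nodes needs 'name' and 'kind' columns", call. = FALSE)
  }
  name <- as.character(nodes$name)
  kind <- as.character(nodes$kind)
  if (anyDuplicated(name)) {
    stop("duplicated node names: ",
         paste(unique(name[duplicated(name)]), collapse = "; "),
         call. = FALSE)
  }
  if (!all(kind %in% c("pt-term", "rubric-category"))) {
    stop("node kind must be 'pt-term' or 'rubric-category'", call. = FALSE)
  }
  parents <- lapply(stats::setNames(name, name), function(nm) {
    p <- as.character(parents[[nm]] %||% character())
    unique(p)
  })
  for (nm in name) {
    dangling <- setdiff(parents[[nm]], name)
    if (length(dangling) > 0L) {
      stop("dangling parent reference at node '", nm, "': ",
           paste(dangling, collapse = "; "), call. = FALSE)
    }
    if (nm %in% parents[[nm]]) {
      stop("node '", nm, "' lists itself as parent", call. = FALSE)
    }
  }
  children <- lapply(stats::setNames(name, name), function(nm) character())
  for (nm in name) {
    for (p in parents[[nm]]) children[[p]] <- c(children[[p]], nm)
  }
  # Kahn topological sort; leftovers form cycles
  indeg <- vapply(parents, length, integer(1L))
  queue <- name[indeg == 0L]
  if (length(queue) == 0L) {
    stop("hierarchy has no root (cycle involving: ",
         paste(name, collapse = "; "), ")", call. = FALSE)
  }
  level <- stats::setNames(rep(NA_integer_, length(name)), name)
  level[queue] <- 1L
  seen <- 0L
  while (length(queue) > 0L) {
    nm <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[nm]]) {
      level[ch] <- max(level[ch], level[nm] + 1L, na.rm = TRUE)
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(name)) {
    stop("hierarchy contains a cycle involving: ",
         paste(name[indeg > 0L], collapse = "; "), call. = FALSE)
  }
  structure(
    list(nodes = data.frame(name = name, kind = kind,
                            level = unname(level[name]),
                            stringsAsFactors = FALSE),
         parents = parents, children = children),
    class = "pt_hierarchy")
}

#' @export
print.pt_hierarchy <- function(x, ...) {
  cat(sprintf("PT hierarchy: %d nodes (%d pt-terms, %d categories), %d roots\n",
              nrow(x$nodes), sum(x$nodes$kind == "pt-term"),
              sum(x$nodes$kind == "rubric-category"),
              length(hierarchy_roots(x))))
  invisible(x)
}

#' Root nodes of a hierarchy
#' @param h A `pt_hierarchy`.
#' @return Character vector of node names with no parents.
#' @export
hierarchy_roots <- function(h) {
  h$nodes$name[vapply(h$parents[h$nodes$name], length, integer(1L)) == 0L]
}

#' Load a hierarchy from JSON
#'
#' The schema is an object with a `nodes` array of
#' `{"name", "kind", "parents": [...]}`. Cycles and dangling parent
#' references are errors naming the offending nodes.
#'
#' @param path Path to a JSON file.
#' @return A validated `pt_hierarchy`.
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$nodes)) stop("hierarchy JSON needs a 'nodes' array",
                               call. = FALSE)
  name <- vapply(raw$nodes, function(nd) as.character(nd$name), character(1L))
  kind <- vapply(raw$nodes, function(nd) as.character(nd$kind), character(1L))
  parents <- stats::setNames(
    lapply(raw$nodes, function(nd) unlist(nd$parents) %||% character()),
    name)
  pt_hierarchy(data.frame(name = name, kind = kind,
                          stringsAsFactors = FALSE), parents)
}

#' Save a hierarchy to JSON
#'
#' `save_hierarchy` then [load_hierarchy()] is the identity.
#'
#' @param h A `pt_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "pt_hierarchy"))
  nodes <- lapply(seq_len(nrow(h$nodes)), function(i) {
    nm <- h$nodes$name[i]
    list(name = jsonlite::unbox(nm),
         kind = jsonlite::unbox(h$nodes$kind[i]),
         parents = as.list(h$parents[[nm]]))
  })
  jsonlite::write_json(list(nodes = nodes), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' The shipped unified PT hierarchy
#'
#' The curated hierarchy fixture: 72 pt-term nodes and 11 rubric-category
#' nodes with 5 roots (three broad categories plus the level-1 terms
#' Multicentre Study and Clinical Study).
#'
#' @return A `pt_hierarchy`.
#' @export
ptrubric_hierarchy <- function() {
  load_hierarchy(system.file("extdata", "pt_hierarchy.json",
                             package = "ptrubric", mustWork = TRUE))
}

assert_terms <- function(h, terms, what = "term") {
  unknown <- setdiff(terms, h$nodes$name)
  if (length(unknown) > 0L) {
    stop("unknown ", what, ": ", paste(unknown, collapse = "; "),
         call. = FALSE)
  }
}

closure <- function(adj, start) {
  out <- character()
  frontier <- adj[[start]]
  while (length(frontier) > 0L) {
    out <- c(out, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), out)
  }
  unique(out)
}

#' Transitive descendants of a term
#'
#' All nodes strictly below `term`, excluding the term itself.
#'
#' @param h A `pt_hierarchy`.
#' @param term Node name.
#' @return Character vector (possibly empty), sorted.
#' @export
descendants <- function(h, term) {
  stopifnot(inherits(h, "pt_hierarchy"))
  assert_terms(h, term)
  sort(closure(h$children, term), method = "radix")
}

#' Transitive ancestors of a term
#'
#' All nodes strictly above `term`, excluding the term itself.
#' `a %in% ancestors(h, b)` iff `b %in% descendants(h, a)`.
#'
#' @inheritParams descendants
#' @return Character vector (possibly empty), sorted.
#' @export
ancestors <- function(h, term) {
  stopifnot(inherits(h, "pt_hierarchy"))
  assert_terms(h, term)
  sort(closure(h$parents, term), method = "radix")
}

#' PubMed-style query expansion
#'
#' Expands a term to itself plus all more specific terms below it in the
#' hierarchy — the expansion PubMed applies automatically to MeSH queries.
#' By default only pt-term descendants are returned (categories are
#' organizational, not indexing targets); the queried term itself is
#' always kept.
#'
#' @param h A `pt_hierarchy`.
#' @param term Node name.
#' @param include_categories Also return rubric-category descendants.
#' @return Sorted character vector; idempotent under re-expansion.
#' @export
expand_query <- function(h, term, include_categories = FALSE) {
  desc <- descendants(h, term)
  if (!include_categories) {
    kinds <- h$nodes$kind[match(desc, h$nodes$name)]
    desc <- desc[kinds == "pt-term"]
  }
  sort(unique(c(term, desc)), method = "radix")
}

#' Hierarchy-consistent tag normalization
#'
#' Post-prediction normalization: each assigned tag is propagated to all
#' its pt-term ancestors, so that (for example) an article tagged Cohort
#' Studies is automatically also tagged Observational Study and Clinical
#' Study regardless of their own scores. Never removes a tag; idempotent
#' and monotone.
#'
#' @param h A `pt_hierarchy`.
#' @param tags Character vector of assigned PT tags (all must exist in
#'   `h`).
#' @param include_categories Also add rubric-category ancestors.
#' @return Sorted character vector, a superset of `tags`.
#' @export
normalize_tags <- function(h, tags, include_categories = FALSE) {
  stopifnot(inherits(h, "pt_hierarchy"))
  tags <- unique(as.character(tags))
  if (length(tags) == 0L) return(character())
  assert_terms(h, tags, what = "tag")
  anc <- unique(unlist(lapply(tags, function(t) ancestors(h, t)),
                       use.names = FALSE))
  if (!include_categories && length(anc) > 0L) {
    kinds <- h$nodes$kind[match(anc, h$nodes$name)]
    anc <- anc[kinds == "pt-term"]
  }
  sort(unique(c(tags, anc)), method = "radix")
}

#' Cross-check a hierarchy against a vocabulary
#'
#' Reports vocabulary terms missing from the hierarchy's pt-terms,
#' hierarchy pt-terms missing from the vocabulary, and structural notes
#' (roots, childless categories). Structural hard violations (cycles,
#' dangling parents) are already rejected at construction.
#'
#' @param h A `pt_hierarchy`.
#' @param vocab Character vector of PT names.
#' @return List with `missing_in_hierarchy`, `missing_in_vocab`, `roots`,
#'   `empty_categories`, `ok`.
#' @export
validate_hierarchy <- function(h, vocab) {
  stopifnot(inherits(h, "pt_hierarchy"))
  vocab <- pt_vocabulary(vocab)
  ptterms <- h$nodes$name[h$nodes$kind == "pt-term"]
  cats <- h$nodes$name[h$nodes$kind == "rubric-category"]
  empty_cats <- cats[vapply(h$children[cats], length, integer(1L)) == 0L]
  missing_in_h <- setdiff(vocab, ptterms)
  missing_in_v <- setdiff(ptterms, vocab)
  list(missing_in_hierarchy = missing_in_h,
       missing_in_vocab = missing_in_v,
       roots = hierarchy_roots(h),
       empty_categories = empty_cats,
       ok = length(missing_in_h) == 0L && length(missing_in_v) == 0L &&
         length(empty_cats) == 0L)
}
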