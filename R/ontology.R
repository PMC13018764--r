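CURIE_PATTERN <- "^[A-Za-z][A-Za-z0-9_]*:[0-9]+$"

#' Load an OBO flat file into an ontology graph
#'
#' Parses the subset of the OBO 1.2/1.4 flat-file format used by the Human
#' Phenotype Ontology (`[Term]` stanzas with `id`, `name`, `is_a`, `alt_id`,
#' `is_obsolete`, `replaced_by`) and builds a validated directed acyclic
#' graph over the non-obsolete terms. Only `is_a` edges are used; other
#' relationship types are ignored. Ancestor closure, minimum up-distances
#' and descendant counts are precomputed; information content is filled in
#' by [compute_ic()] (intrinsic mode is computed eagerly as the default).
#'
#' @param path Path to an OBO flat file.
#' @param root Optional CURIE naming the root term. When omitted the unique
#'   parentless non-obsolete term is used; multiple parentless terms without
#'   an explicit `root` are an error.
#' @return An object of class `ontology_graph`: a list with elements
#'   `ids`, `name`, `parents`, `children`, `ancestors` (proper-ancestor
#'   closure), `updist` (named integer vectors of minimum parent-edge
#'   distances to each proper ancestor), `n_desc` (descendant counts
#'   including self), `ic`, `ic_mode`, `root`, `alt` (alt_id to primary id
#'   map), and `replaced` (obsolete id to replacement map).
#' @examples
#' g <- load_obo(system.file("extdata", "mini_hpo.obo", package = "phenopair"))
#' g$root
#' @export
load_obo <- function(path, root = NULL) {
  if (!file.exists(path)) {
    stop2("phenopair_io_error", "OBO file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")

  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <<- cur
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      flush()
      cur <- list(id = NULL, name = NA_character_, parents = character(),
                  alt_ids = character(), obsolete = FALSE,
                  replaced_by = NA_character_)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {          # any other stanza type ends a term
      flush(); cur <- NULL; in_term <- FALSE
      next
    }
    if (!in_term || ln == "" || !grepl(":", ln, fixed = TRUE)) next
    key <- sub(":.*$", "", ln)
    val <- sub("^[^:]+:\\s*", "", ln)
    val <- sub("\\s*!.*$", "", val)   # strip trailing OBO comments
    switch(key,
      id = { cur$id <- val },
      name = { cur$name <- val },
      is_a = { cur$parents <- c(cur$parents, val) },
      alt_id = { cur$alt_ids <- c(cur$alt_ids, val) },
      is_obsolete = { cur$obsolete <- identical(tolower(val), "true") },
      replaced_by = { cur$replaced_by <- val },
      NULL)
  }
  flush()

  if (length(terms) == 0L) {
    stop2("phenopair_validation_error", "no [Term] stanzas found in ", path)
  }
  ids_all <- names(terms)
  bad <- ids_all[!grepl(CURIE_PATTERN, ids_all)]
  if (length(bad)) {
    stop2("phenopair_validation_error",
          "term ids are not PREFIX:digits CURIEs: ", toString(bad))
  }

  obsolete <- vapply(terms, function(t) isTRUE(t$obsolete), logical(1))
  live <- terms[!obsolete]
  ids <- names(live)
  parents <- lapply(live, function(t) unique(t$parents))
  names(parents) <- ids

  unknown <- setdiff(unique(unlist(parents)), ids)
  if (length(unknown)) {
    stop2("phenopair_validation_error",
          "is_a references unknown or obsolete ids: ", toString(unknown))
  }

  # Kahn topological sort over parent -> child edges; leftovers mean a cycle.
  n_par <- vapply(parents, length, integer(1))
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  roots <- ids[n_par == 0L]
  if (is.null(root)) {
    if (length(roots) != 1L) {
      stop2("phenopair_validation_error",
            "expected exactly one parentless root term, found: ",
            toString(roots), " (pass `root` explicitly)")
    }
    root <- roots
  } else {
    if (!root %in% ids) {
      stop2("phenopair_validation_error", "missing root term: ", root)
    }
    stray <- setdiff(roots, root)
    if (length(stray)) {
      stop2("phenopair_validation_error",
            "terms cannot reach root ", root, ": ", toString(stray))
    }
  }

  topo <- character(0)
  indeg <- n_par
  queue <- roots
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(ids)) {
    cyc <- setdiff(ids, topo)
    edges <- unlist(lapply(cyc, function(id) {
      paste(intersect(parents[[id]], cyc), "->", id)
    }))
    stop2("phenopair_validation_error",
          "cycle detected among is_a edges: ", toString(edges))
  }

  # Minimum up-distance to every proper ancestor, in topological order.
  updist <- stats::setNames(vector("list", length(ids)), ids)
  for (id in topo) {
    d <- integer(0)
    for (p in parents[[id]]) {
      cand <- c(stats::setNames(1L, p), updist[[p]] + 1L)
      for (a in names(cand)) {
        if (is.na(d[a]) || cand[[a]] < d[[a]]) d[a] <- cand[[a]]
      }
    }
    updist[[id]] <- d
  }
  ancestors <- lapply(updist, function(u) {
    if (length(u)) names(u) else character(0)
  })

  anc_tab <- table(unlist(ancestors, use.names = FALSE))
  n_desc <- stats::setNames(rep(1L, length(ids)), ids)
  n_desc[names(anc_tab)] <- n_desc[names(anc_tab)] + as.integer(anc_tab)

  alt <- character(0)
  for (id in ids) {
    for (a in live[[id]]$alt_ids) alt[a] <- id
  }
  replaced <- character(0)
  for (t in terms[obsolete]) {
    if (!is.na(t$replaced_by)) replaced[t$id] <- t$replaced_by
    else replaced[t$id] <- NA_character_
  }

  g <- structure(list(
    ids = ids,
    name = vapply(live, function(t) t$name, character(1)),
    parents = parents,
    children = lapply(children, unique),
    ancestors = ancestors,
    updist = updist,
    n_desc = n_desc,
    ic = NULL,
    ic_mode = NA_character_,
    root = root,
    alt = alt,
    replaced = replaced,
    obsolete = names(terms)[obsolete],
    simcache = new.env(parent = emptyenv())
  ), class = "ontology_graph")
  compute_ic(g, mode = "intrinsic")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, root %s (%s), IC mode: %s\n",
              length(x$ids), x$root, x$name[[x$root]], x$ic_mode))
  invisible(x)
}

#' Resolve a term id to its primary id
#'
#' Maps alternate ids to their primary term and obsolete ids to their
#' `replaced_by` target. Primary ids resolve to themselves.
#'
#' @param graph An `ontology_graph`.
#' @param ids Character vector of CURIEs.
#' @param on_unknown `"error"` to fail on unresolvable ids, `"na"` to return
#'   `NA` for them so the caller can warn-and-drop.
#' @return Character vector of primary ids (with `NA` for unresolvable ids
#'   under `on_unknown = "na"`).
#' @export
resolve_term <- function(graph, ids, on_unknown = c("error", "na")) {
  on_unknown <- match.arg(on_unknown)
  out <- ifelse(ids %in% graph$ids, ids, NA_character_)
  miss <- is.na(out)
  if (any(miss)) {
    hit <- graph$alt[ids[miss]]
    out[miss] <- unname(hit)
  }
  miss <- is.na(out)
  if (any(miss)) {
    rep <- graph$replaced[ids[miss]]
    rep[!rep %in% graph$ids] <- NA_character_
    out[miss] <- unname(rep)
  }
  if (anyNA(out) && on_unknown == "error") {
    stop2("phenopair_unknown_term",
          "unknown term id(s): ", toString(unique(ids[is.na(out)])))
  }
  out
}

assert_primary <- function(graph, ids) {
  bad <- setdiff(ids, graph$ids)
  if (length(bad)) {
    stop2("phenopair_unknown_term", "unknown term id(s): ", toString(bad))
  }
  invisible(ids)
}

#' Minimum ancestor path length between two terms
#'
#' Returns 0 when `a == b`, the minimum number of parent (`is_a`) edges
#' separating the two terms when one is a proper ancestor of the other,
#' and `NA` when the terms are unrelated (neither is an ancestor of the
#' other). When multiple parentage paths exist the minimum is taken.
#'
#' @inheritParams resolve_term
#' @param a,b Primary term ids.
#' @return A non-negative integer, or `NA_integer_` for unrelated terms.
#' @examples
#' g <- load_obo(system.file("extdata", "mini_hpo.obo", package = "phenopair"))
#' ancestor_path_length(g, "HP:0000539", "HP:0025573")  # 2
#' @export
ancestor_path_length <- function(graph, a, b) {
  assert_primary(graph, c(a, b))
  if (a == b) return(0L)
  da <- graph$updist[[b]][a]      # distance up from b to a, if a is ancestor
  if (!is.na(da)) return(unname(da))
  db <- graph$updist[[a]][b]
  if (!is.na(db)) return(unname(db))
  NA_integer_
}

#' Compute information content for every term
#'
#' Intrinsic mode uses the descendant-count estimator
#' \eqn{IC(t) = -\log(n_{desc}(t) / n_{desc}(root))}: a term subsuming few
#' terms is informative, the root carries no information. Corpus mode counts
#' term usages (annotations), propagates counts to all ancestors, and sets
#' \eqn{IC(t) = -\log(freq(t)/freq(root))}; terms never used (directly or
#' below) get infinite IC. In both modes `ic[root] == 0` and IC is
#' non-decreasing from parent to child.
#'
#' @inheritParams resolve_term
#' @param mode `"intrinsic"` (default) or `"corpus"`.
#' @param corpus For corpus mode, a character vector (multiset) of term
#'   usages; ids are resolved first and unresolvable ids are dropped with a
#'   warning reporting the count.
#' @return The graph with `ic` and `ic_mode` replaced (pairwise similarity
#'   cache invalidated).
#' @export
compute_ic <- function(graph, mode = c("intrinsic", "corpus"), corpus = NULL) {
  mode <- match.arg(mode)
  if (mode == "intrinsic") {
    ic <- -log(graph$n_desc / graph$n_desc[[graph$root]])
  } else {
    if (is.null(corpus) || length(corpus) == 0L) {
      stop2("phenopair_validation_error", "corpus mode requires a non-empty corpus")
    }
    res <- resolve_term(graph, corpus, on_unknown = "na")
    n_drop <- sum(is.na(res))
    if (n_drop > 0L) {
      warning(sprintf("dropped %d corpus term(s) absent from the ontology", n_drop))
      res <- res[!is.na(res)]
      if (length(res) == 0L) {
        stop2("phenopair_validation_error", "no corpus terms resolved")
      }
    }
    counts <- stats::setNames(rep(0, length(graph$ids)), graph$ids)
    tab <- table(res)
    counts[names(tab)] <- as.numeric(tab)
    freq <- counts
    for (id in graph$ids) {
      if (counts[[id]] > 0) {
        anc <- graph$ancestors[[id]]
        freq[anc] <- freq[anc] + counts[[id]]
      }
    }
    ic <- -log(freq / freq[[graph$root]])   # freq 0 -> Inf
  }
  ic[[graph$root]] <- 0
  graph$ic <- ic
  graph$ic_mode <- mode
  graph$simcache <- new.env(parent = emptyenv())
  graph
}

#' Lin semantic similarity between two terms
#'
#' \eqn{sim(a,b) = 2\,IC(MICA)/(IC(a)+IC(b))} where the MICA (most
#' informative common ancestor) search includes the terms themselves.
#' Identical terms score exactly 1; pairs whose only common ancestor is the
#' root score 0; when `IC(a) + IC(b) == 0` the similarity is defined as 0.
#'
#' @inheritParams ancestor_path_length
#' @return A similarity in `[0, 1]`.
#' @export
lin_similarity <- function(graph, a, b) {
  assert_primary(graph, c(a, b))
  if (a == b) return(1)
  key <- if (a < b) paste0(a, "|", b) else paste0(b, "|", a)
  hit <- graph$simcache[[key]]
  if (!is.null(hit)) return(hit)
  common <- intersect(c(a, graph$ancestors[[a]]), c(b, graph$ancestors[[b]]))
  mica_ic <- max(graph$ic[common])
  denom <- graph$ic[[a]] + graph$ic[[b]]
  val <- if (denom == 0 || !is.finite(denom)) 0 else
    min(1, max(0, 2 * mica_ic / denom))
  graph$simcache[[key]] <- val
  val
}

#' Proper descendants of a term
#'
#' @inheritParams ancestor_path_length
#' @param term A primary term id.
#' @return Character vector of all terms having `term` in their ancestor
#'   closure (excluding `term` itself).
#' @export
descendants <- function(graph, term) {
  assert_primary(graph, term)
  graph$ids[vapply(graph$ancestors, function(a) term %in% a, logical(1))]
}

stop2 <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
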