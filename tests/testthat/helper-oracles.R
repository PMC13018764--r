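# Fixture builders and independent brute-force oracles. Oracles never call
# the package code paths they check (they use only raw parent lists and the
# graph's precomputed IC table).

fixture_graph <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_fixture_ontology()
    g
  }
})

# Serialise a parent list (named list id -> character vector of parent ids)
# to OBO text and load it.
write_obo <- function(parents, path = tempfile(fileext = ".obo"),
                      alt = NULL, obsolete = NULL, names_ = NULL) {
  lines <- c("format-version: 1.2", "")
  for (id in names(parents)) {
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: ", if (!is.null(names_[[id]])) names_[[id]]
                      else paste("term", id)))
    if (!is.null(alt[[id]])) {
      lines <- c(lines, paste0("alt_id: ", alt[[id]]))
    }
    for (p in parents[[id]]) lines <- c(lines, paste0("is_a: ", p))
    lines <- c(lines, "")
  }
  for (ob in names(obsolete)) {
    lines <- c(lines, "[Term]", paste0("id: ", ob), "name: obsolete term",
               "is_obsolete: true")
    if (!is.na(obsolete[[ob]])) {
      lines <- c(lines, paste0("replaced_by: ", obsolete[[ob]]))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  path
}

# Random DAG over n nodes: node 1 is the root; each later node picks 1-2
# parents among earlier nodes, guaranteeing acyclicity and reachability.
random_dag_parents <- function(n) {
  ids <- sprintf("TT:%07d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  parents[[1]] <- character(0)
  for (i in seq_len(n)[-1]) {
    k <- min(i - 1L, sample(1:2, 1L))
    parents[[i]] <- ids[sample.int(i - 1L, k)]
  }
  parents
}

# Brute-force transitive closure (proper ancestors) by repeated DFS.
brute_closure <- function(parents) {
  lapply(parents, function(p) {
    seen <- character(0)
    stack <- p
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (!v %in% seen) {
        seen <- c(seen, v)
        stack <- c(stack, parents[[v]])
      }
    }
    sort(seen)
  })
}

# Brute-force Lin similarity: enumerate common ancestors (including the
# terms), take max IC from the graph's table.
brute_lin <- function(parents, ic, a, b) {
  if (a == b) return(1)
  clo <- brute_closure(parents)
  common <- intersect(c(a, clo[[a]]), c(b, clo[[b]]))
  denom <- ic[[a]] + ic[[b]]
  if (denom == 0 || !is.finite(denom)) return(0)
  2 * max(ic[common]) / denom
}

# Brute-force best-match-average set similarity on top of brute_lin.
brute_set_sim <- function(parents, ic, A, B) {
  m <- outer(A, B, Vectorize(function(x, y) brute_lin(parents, ic, x, y)))
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

# Minimal two-branch ontology whose only common ancestor of the leaves is
# the root (so cross-branch Lin similarity is exactly 0).
two_branch_graph <- function() {
  load_obo(write_obo(list(
    "ZZ:0000001" = character(0),
    "ZZ:0000002" = "ZZ:0000001",
    "ZZ:0000003" = "ZZ:0000001",
    "ZZ:0000004" = "ZZ:0000002",
    "ZZ:0000005" = "ZZ:0000003")))
}

# Linear chain root -> ... -> leaf with k terms.
chain_graph <- function(k) {
  ids <- sprintf("CC:%07d", seq_len(k))
  parents <- stats::setNames(
    c(list(character(0)), as.list(ids[-k])), ids)
  load_obo(write_obo(parents))
}

write_cohort_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Rebuild a cohort from a records data.frame through the public reader.
new_cohort_from_records <- function(rec) {
  read_cohort(write_cohort_tsv(rec[c("participant_id", "source", "system",
                                     "term_id")]),
              graph = fixture_graph())
}

make_records <- function(...) {
  rows <- list(...)
  if (length(rows) == 0L) {
    return(data.frame(participant_id = character(0), source = character(0),
                      system = character(0), term_id = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(participant_id = r[[1]], source = r[[2]], system = r[[3]],
               term_id = r[[4]], stringsAsFactors = FALSE)
  }))
}
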