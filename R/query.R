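#' Descendant-closure presence query
#'
#' True iff any term in `terms` equals `root_term` or is a descendant of it
#' at any depth ("a child code" in the clinical sense covers the whole
#' subtree, e.g. seizure subtypes sitting two levels below HP:0001250).
#'
#' @param graph An `ontology_graph`.
#' @param terms Character vector of primary term ids (may be empty).
#' @param root_term Primary term id rooting the phenotype of interest.
#' @return Logical scalar.
#' @export
has_phenotype <- function(graph, terms, root_term) {
  assert_primary(graph, root_term)
  if (length(terms) == 0L) return(FALSE)
  assert_primary(graph, terms)
  any(terms == root_term |
        vapply(terms, function(t) root_term %in% graph$ancestors[[t]],
               logical(1)))
}

#' Stratify participants by which source reported a phenotype
#'
#' Evaluates [has_phenotype()] on each participant's combined-scope PRD and
#' CRD term sets and assigns one of four exclusive labels: `both`,
#' `PRD only`, `CRD only`, `absent`.
#'
#' @param cohort A `phenotype_cohort`.
#' @inheritParams has_phenotype
#' @return Data.frame `participant_id`, `status`.
#' @export
stratify_by_source <- function(cohort, graph, root_term) {
  parts <- sort(unique(cohort$records$participant_id))
  status <- vapply(parts, function(p) {
    in_prd <- has_phenotype(graph, term_set(cohort, p, "PRD"), root_term)
    in_crd <- has_phenotype(graph, term_set(cohort, p, "CRD"), root_term)
    if (in_prd && in_crd) "both"
    else if (in_prd) "PRD only"
    else if (in_crd) "CRD only"
    else "absent"
  }, character(1))
  data.frame(participant_id = parts, status = unname(status),
             stringsAsFactors = FALSE)
}

#' Classify a present phenotype as root-only or subtyped
#'
#' Given a term set known to contain the phenotype (see [has_phenotype()]),
#' returns the proper-descendant subtype terms present; when only the root
#' term itself appears the participant is `root_only`. Presence of the root
#' term does not mask subtypes.
#'
#' @inheritParams has_phenotype
#' @return List with `type` (`"root_only"` or `"subtyped"`) and `subtypes`
#'   (character vector, empty for root_only).
#' @export
classify_subtype <- function(graph, terms, root_term) {
  if (!has_phenotype(graph, terms, root_term)) {
    stop2("phenopair_validation_error",
          "classify_subtype called on a term set without ", root_term)
  }
  sub <- sort(intersect(terms, descendants(graph, root_term)))
  list(type = if (length(sub)) "subtyped" else "root_only", subtypes = sub)
}

#' Participant-level term frequency table
#'
#' Counts, for each term, the number of participants carrying it in the
#' chosen source (`combined` = either source; a term reported by both
#' sources counts once per participant). Sorted by descending count, ties
#' broken by term id.
#'
#' @param cohort A `phenotype_cohort`.
#' @param source_filter `"combined"`, `"PRD"` or `"CRD"`.
#' @return Data.frame `term_id`, `count`.
#' @export
term_frequency <- function(cohort, source_filter = c("combined", "PRD", "CRD")) {
  source_filter <- match.arg(source_filter)
  rec <- cohort$records
  if (source_filter != "combined") {
    rec <- rec[rec$source == source_filter, , drop = FALSE]
  }
  if (nrow(rec) == 0L) {
    return(data.frame(term_id = character(0), count = integer(0)))
  }
  pt <- unique(rec[c("participant_id", "term_id")])
  tab <- table(pt$term_id)
  out <- data.frame(term_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$term_id), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Source-unique vocabulary sizes per body system
#'
#' For each system, counts the terms present in one source's cohort-wide
#' vocabulary for that system but absent from the other source's.
#'
#' @param cohort A `phenotype_cohort`.
#' @return Data.frame `system`, `source`, `n_unique_to_source`.
#' @export
unique_terms_by_system <- function(cohort) {
  rec <- cohort$records
  systems <- sort(unique(rec$system))
  rows <- lapply(systems, function(sys) {
    vocab <- lapply(SOURCES, function(src) {
      unique(rec$term_id[rec$system == sys & rec$source == src])
    })
    names(vocab) <- SOURCES
    data.frame(system = sys, source = SOURCES,
               n_unique_to_source = c(
                 length(setdiff(vocab$PRD, vocab$CRD)),
                 length(setdiff(vocab$CRD, vocab$PRD))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(system = character(0),
                                      source = character(0),
                                      n_unique_to_source = integer(0))
  out
}
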