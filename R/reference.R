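#' Read a gene-to-phenotype reference table
#'
#' Loads a G2P-style TSV with columns `gene` and `hpo_ids` (comma-separated
#' CURIEs), resolves every id to its primary term, drops unresolvable ids
#' with a warning, and deduplicates each gene's set. Per-gene term counts
#' are attached as an attribute, since reference list sizes vary widely and
#' similarity against a large list is systematically higher.
#'
#' @param path TSV path.
#' @param graph An `ontology_graph`.
#' @return Named list (class `g2p_reference`) mapping gene symbol to a
#'   character vector of primary term ids; attribute `term_counts`.
#' @export
read_reference <- function(path, graph) {
  df <- read_table_any(path, c("gene", "hpo_ids"))
  if (anyDuplicated(df$gene)) {
    stop2("phenopair_validation_error", path, ": duplicate gene rows")
  }
  n_drop <- 0L
  ref <- stats::setNames(lapply(seq_len(nrow(df)), function(i) {
    ids <- trimws(strsplit(df$hpo_ids[i], ",", fixed = TRUE)[[1]])
    ids <- ids[ids != ""]
    res <- resolve_term(graph, ids, on_unknown = "na")
    n_drop <<- n_drop + sum(is.na(res))
    sort(unique(res[!is.na(res)]))
  }), df$gene)
  if (n_drop > 0L) {
    warning(sprintf("dropped %d unresolvable reference term(s)", n_drop))
  }
  empty <- vapply(ref, length, integer(1)) == 0L
  if (any(empty)) {
    warning("dropped gene(s) with empty term sets: ",
            toString(names(ref)[empty]))
    ref <- ref[!empty]
  }
  structure(ref, class = "g2p_reference",
            term_counts = vapply(ref, length, integer(1)))
}

#' Per-participant similarity against a gene's reference phenotype list
#'
#' For every participant carrying `gene`, computes the best-match-average
#' Lin similarity between the participant's term set from the chosen source
#' (`PRD`, `CRD`, or their union as `combined`) and the gene's reference
#' set. Participants with an empty source set are skipped and reported.
#'
#' @param cohort A `phenotype_cohort` with metadata.
#' @param graph An `ontology_graph` with IC computed.
#' @param ref A `g2p_reference`.
#' @param gene Gene symbol present in `ref`.
#' @param source `"PRD"`, `"CRD"` or `"combined"`.
#' @return Data.frame `participant_id`, `source`, `similarity`; attribute
#'   `n_skipped` counts empty-set participants.
#' @export
reference_similarity <- function(cohort, graph, ref, gene,
                                 source = c("combined", "PRD", "CRD")) {
  source <- match.arg(source)
  if (!gene %in% names(ref)) {
    stop2("phenopair_validation_error", "gene not in reference: ", gene)
  }
  if (is.null(cohort$meta)) {
    stop2("phenopair_validation_error", "cohort has no participant metadata")
  }
  parts <- cohort$meta$participant_id[cohort$meta$gene == gene]
  if (length(parts) == 0L) {
    stop2("phenopair_validation_error", "no participants carry gene ", gene)
  }
  rset <- ref[[gene]]
  sets <- lapply(parts, function(p) {
    if (source == "combined") {
      union(term_set(cohort, p, "PRD"), term_set(cohort, p, "CRD"))
    } else {
      term_set(cohort, p, source)
    }
  })
  keep <- vapply(sets, length, integer(1)) > 0L
  sim <- vapply(sets[keep], function(s) set_similarity(graph, s, rset),
                numeric(1))
  structure(data.frame(participant_id = parts[keep],
                       source = rep(source, sum(keep)),
                       similarity = sim, stringsAsFactors = FALSE),
            n_skipped = sum(!keep))
}

#' Compare PRD, CRD and combined reference similarity for one gene
#'
#' Runs a Welch one-way ANOVA across the three per-participant similarity
#' groups (PRD vs reference, CRD vs reference, combined vs reference).
#' When the global test is significant at `alpha`, all pairwise Welch t
#' tests with Holm adjustment follow; otherwise only the ANOVA row is
#' returned.
#'
#' @inheritParams reference_similarity
#' @param alpha Gate for running pairwise follow-ups (default 0.05).
#' @return Data.frame of test results with family `"reference:<gene>"`;
#'   the first row is the ANOVA (scope `"ANOVA"`).
#' @export
compare_sources_to_reference <- function(cohort, graph, ref, gene,
                                         alpha = 0.05) {
  groups <- lapply(c(PRD = "PRD", CRD = "CRD", combined = "combined"),
                   function(s) {
    reference_similarity(cohort, graph, ref, gene, source = s)$similarity
  })
  family <- paste0("reference:", gene)
  aov <- welch_anova(groups)
  out <- data.frame(family = family, scope = "ANOVA",
                    statistic = aov$statistic, p_raw = aov$p.value,
                    p_adjusted = aov$p.value, method = "welch_anova",
                    n = sum(lengths(groups)), stringsAsFactors = FALSE)
  if (!is.na(aov$p.value) && aov$p.value < alpha) {
    out <- rbind(out, pairwise_welch_holm(groups, family = family))
  }
  out
}
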