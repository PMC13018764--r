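#' Quantity score: number of distinct HPO terms
#'
#' @param terms Character vector of term ids.
#' @return Count of distinct terms.
#' @export
quantity_score <- function(terms) {
  length(unique(terms))
}

#' Detail scores: ancestor-distance credit for the more specific source
#'
#' For every pair of one parent-reported (PRD) and one clinician-reported
#' (CRD) term, if one term is a proper ancestor of the other, the source
#' holding the *descendant* (more specific) term is credited with the
#' minimum number of ontology levels separating the pair. Unrelated pairs
#' and identical terms contribute nothing. By default all qualifying pairs
#' accumulate; `best_pair_only = TRUE` restricts each term to its single
#' largest increment (sensitivity analysis).
#'
#' @param graph An `ontology_graph`.
#' @param prd,crd Character vectors of primary term ids.
#' @param best_pair_only Cap each term at its largest single increment.
#' @return Named integer vector `c(prd = ..., crd = ...)`.
#' @examples
#' g <- load_obo(system.file("extdata", "mini_hpo.obo", package = "phenopair"))
#' detail_scores(g, prd = "HP:0025573", crd = "HP:0000545")   # c(prd=1, crd=0)
#' detail_scores(g, prd = "HP:0025573", crd = "HP:0000539")   # c(prd=2, crd=0)
#' @export
detail_scores <- function(graph, prd, crd, best_pair_only = FALSE) {
  prd <- unique(prd); crd <- unique(crd)
  assert_primary(graph, c(prd, crd))
  credit <- function(desc_terms, anc_terms) {
    # desc_terms holds the potential descendants being credited
    per_term <- vapply(desc_terms, function(t) {
      up <- graph$updist[[t]][anc_terms]
      up <- up[!is.na(up)]
      if (!length(up)) return(0L)
      if (best_pair_only) max(up) else sum(up)
    }, integer(1))
    sum(per_term)
  }
  c(prd = credit(prd, crd), crd = credit(crd, prd))
}

#' Best-match-average Lin similarity between two term sets
#'
#' Computes the symmetric best-match average: for each term of `a` the
#' maximum Lin similarity over `b` is taken and averaged, likewise from `b`
#' to `a`, and the two directional averages are averaged. Identical
#' nonempty sets score exactly 1. Either set empty returns `NA` (the
#' participant is excluded upstream by the pairing rule).
#'
#' @inheritParams detail_scores
#' @param a,b Character vectors of primary term ids.
#' @return A similarity in `[0, 1]`, or `NA_real_` if either set is empty.
#' @export
set_similarity <- function(graph, a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  assert_primary(graph, c(a, b))
  m <- matrix(0, length(a), length(b))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) m[i, j] <- lin_similarity(graph, a[i], b[j])
  }
  (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
}

category_of <- function(prd, crd) {
  ifelse(prd > crd, "Parent more", ifelse(crd > prd, "Doctor more", "Equal"))
}

#' Per-participant score table across scopes
#'
#' For each requested scope (each body system and/or `"combined"`) and each
#' paired participant, computes the quantity of distinct terms per source,
#' the two detail scores, the best-match-average Lin set similarity, and
#' the strict-inequality comparison categories (`Parent more`,
#' `Doctor more`, `Equal`).
#'
#' @param cohort A `phenotype_cohort`.
#' @param graph An `ontology_graph` with IC computed.
#' @param scopes Character vector of scopes; default all systems present in
#'   the cohort plus `"combined"`.
#' @param rule Pairing rule for the combined scope, see
#'   [paired_participants()].
#' @param similarity,detail Set `FALSE` to skip the similarity or detail
#'   columns (fast paths for category-only analyses such as calibration
#'   simulations); skipped columns are `NA`.
#' @param best_pair_only Passed to [detail_scores()].
#' @return A data.frame of class `score_table` with one row per paired
#'   participant and scope; `gene` and `gene_group` columns are joined from
#'   cohort metadata when present.
#' @export
score_table <- function(cohort, graph, scopes = NULL,
                        rule = c("strict", "lenient"),
                        similarity = TRUE, detail = TRUE,
                        best_pair_only = FALSE) {
  rule <- match.arg(rule)
  if (is.null(scopes)) {
    scopes <- c(sort(unique(cohort$records$system)), "combined")
  }
  rows <- list()
  rec_all <- cohort$records
  for (scope in scopes) {
    pp <- paired_participants(cohort, scope, rule = rule)
    rec <- if (scope == "combined") rec_all else
      rec_all[rec_all$system == scope, , drop = FALSE]
    sets <- split(rec$term_id, paste(rec$participant_id, rec$source))
    for (p in pp) {
      prd <- sets[[paste(p, "PRD")]]
      crd <- sets[[paste(p, "CRD")]]
      prd <- if (is.null(prd)) character(0) else sort(unique(prd))
      crd <- if (is.null(crd)) character(0) else sort(unique(crd))
      det <- if (detail) {
        detail_scores(graph, prd, crd, best_pair_only = best_pair_only)
      } else {
        c(prd = NA_integer_, crd = NA_integer_)
      }
      sim <- if (similarity) set_similarity(graph, prd, crd) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = p, scope = scope,
        quantity_prd = length(prd), quantity_crd = length(crd),
        detail_prd = unname(det[["prd"]]), detail_crd = unname(det[["crd"]]),
        similarity = sim,
        quantity_category = category_of(length(prd), length(crd)),
        detail_category = if (detail) category_of(det[["prd"]], det[["crd"]])
                          else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    participant_id = character(0), scope = character(0),
    quantity_prd = integer(0), quantity_crd = integer(0),
    detail_prd = integer(0), detail_crd = integer(0),
    similarity = numeric(0), quantity_category = character(0),
    detail_category = character(0), stringsAsFactors = FALSE)
  if (!is.null(cohort$meta) && nrow(out)) {
    i <- match(out$participant_id, cohort$meta$participant_id)
    out$gene <- cohort$meta$gene[i]
    out$gene_group <- cohort$meta$gene_group[i]
  }
  class(out) <- c("score_table", "data.frame")
  out
}

#' Participants with the lowest combined similarity
#'
#' Ranking helper supporting manual review of the least concordant
#' participants.
#'
#' @param scores A `score_table`.
#' @param k Number of participants to return.
#' @param scope Scope to rank within (default `"combined"`).
#' @return The `k` lowest-similarity rows, ascending.
#' @export
lowest_similarity <- function(scores, k = 20L, scope = "combined") {
  s <- scores[scores$scope == scope & !is.na(scores$similarity), , drop = FALSE]
  s <- s[order(s$similarity, s$participant_id), , drop = FALSE]
  utils::head(s, k)
}

#' Count comparison categories per group
#'
#' Tabulates `Parent more` / `Doctor more` / `Equal` for the chosen score
#' within each level of a grouping column (`scope` for the per-system
#' analysis, `gene_group` or `gene` for the gene-level analyses; the latter
#' two are counted at the combined scope only).
#'
#' @param scores A `score_table`.
#' @param score `"quantity"` or `"detail"`.
#' @param by Grouping column: `"scope"`, `"gene_group"` or `"gene"`.
#' @return A data.frame with columns `group`, `n_parent_more`,
#'   `n_doctor_more`, `n_equal`, `n`.
#' @export
count_categories <- function(scores, score = c("quantity", "detail"),
                             by = c("scope", "gene_group", "gene")) {
  score <- match.arg(score)
  by <- match.arg(by)
  cat_col <- paste0(score, "_category")
  s <- scores
  if (by != "scope") {
    if (is.null(s[[by]])) {
      stop2("phenopair_validation_error",
            "score table has no '", by, "' column (cohort had no metadata)")
    }
    s <- s[s$scope == "combined" & !is.na(s[[by]]) & s[[by]] != "", ,
           drop = FALSE]
  }
  groups <- sort(unique(s[[by]]))
  out <- do.call(rbind, lapply(groups, function(g) {
    cats <- s[[cat_col]][s[[by]] == g]
    data.frame(group = g,
               n_parent_more = sum(cats == "Parent more"),
               n_doctor_more = sum(cats == "Doctor more"),
               n_equal = sum(cats == "Equal"),
               n = length(cats), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(group = character(0),
                                      n_parent_more = integer(0),
                                      n_doctor_more = integer(0),
                                      n_equal = integer(0), n = integer(0))
  out
}

#' McNemar tests over category counts with FDR adjustment
#'
#' Runs [mcnemar_test()] on the discordant counts (`Parent more` vs
#' `Doctor more`) of every group and adjusts the raw p values by
#' Benjamini-Hochberg within the family. Groups with no discordant pairs
#' are reported with `NA` statistics rather than failing the family.
#'
#' @param counts Output of [count_categories()].
#' @param family Family label recorded on each row (e.g.
#'   `"quantity:systems"`).
#' @param continuity Apply the continuity correction (default TRUE,
#'   matching the conventional paired chi-square test).
#' @return A data.frame of test results: `family`, `scope`, `statistic`,
#'   `p_raw`, `p_adjusted`, `method`, `n`.
#' @export
compare_categories <- function(counts, family, continuity = TRUE) {
  res <- lapply(seq_len(nrow(counts)), function(i) {
    b <- counts$n_parent_more[i]; cc <- counts$n_doctor_more[i]
    if (b + cc == 0L) return(c(NA_real_, NA_real_))
    tst <- mcnemar_test(b, cc, continuity = continuity)
    c(tst$statistic, tst$p.value)
  })
  stat <- vapply(res, `[`, numeric(1), 1L)
  p <- vapply(res, `[`, numeric(1), 2L)
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- bh_adjust(p[ok])
  data.frame(family = family, scope = counts$group, statistic = stat,
             p_raw = p, p_adjusted = padj,
             method = paste0("mcnemar_chisq",
                             if (continuity) "_cc" else "", "+BH"),
             n = counts$n, stringsAsFactors = FALSE)
}
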