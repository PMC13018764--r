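DEFAULT_SYSTEMS <- c("cardiac", "dental", "endocrine", "ENT",
                     "gastroenterology", "immunology", "neurology",
                     "renal", "respiratory", "vision")
SOURCES <- c("PRD", "CRD")

new_cohort <- function(records, meta, report = list()) {
  rownames(records) <- NULL
  if (!is.null(meta)) rownames(meta) <- NULL
  structure(list(records = records, meta = meta, report = report),
            class = "phenotype_cohort")
}

#' @export
print.phenotype_cohort <- function(x, ...) {
  cat(sprintf(
    "phenotype_cohort: %d records, %d participants, %d systems\n",
    nrow(x$records), length(unique(x$records$participant_id)),
    length(unique(x$records$system))))
  invisible(x)
}

read_table_any <- function(path, required) {
  if (!file.exists(path)) {
    stop2("phenopair_io_error", "input file not found: ", path)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0L) {
      df <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(required)), required))
    }
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, colClasses = "character",
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop2("phenopair_validation_error", path, ": missing column(s): ",
          toString(missing_cols))
  }
  for (cl in required) df[[cl]] <- as.character(df[[cl]])
  df[required]
}

#' Read a paired-source phenotype cohort
#'
#' Loads long-format phenotype records (one row per participant, source,
#' body system and HPO term) plus optional participant metadata (gene and
#' gene group), resolves every term to its primary non-obsolete id via
#' [resolve_term()], removes duplicate (participant, source, system, term)
#' tuples, and attaches a load report with kept/dropped counts per reason.
#'
#' @param records_path TSV or JSON file with columns `participant_id`,
#'   `source` (`PRD`/`CRD`), `system`, `term_id`.
#' @param meta_path Optional TSV/JSON file with columns `participant_id`,
#'   `gene`, `gene_group` (one row per participant).
#' @param graph An `ontology_graph` used to validate and resolve terms.
#' @param on_unknown `"drop"` (default) records unresolvable terms in the
#'   load report and continues; `"fail"` stops listing the offending ids.
#' @param systems Controlled vocabulary of body-system labels; rows using a
#'   label outside it are an error. `NULL` accepts any label.
#' @return A `phenotype_cohort`: list with `records` (data.frame), `meta`
#'   (data.frame or NULL) and `report` (named counts).
#' @export
read_cohort <- function(records_path, meta_path = NULL, graph,
                        on_unknown = c("drop", "fail"),
                        systems = DEFAULT_SYSTEMS) {
  on_unknown <- match.arg(on_unknown)
  rec <- read_table_any(records_path,
                        c("participant_id", "source", "system", "term_id"))

  blank <- which(apply(rec == "" | is.na(rec), 1L, any))
  if (length(blank)) {
    stop2("phenopair_validation_error", records_path,
          ": malformed row(s) with empty fields at line(s): ",
          toString(blank + 1L))
  }
  bad_src <- which(!rec$source %in% SOURCES)
  if (length(bad_src)) {
    stop2("phenopair_validation_error", records_path,
          ": source must be PRD or CRD at line(s): ", toString(bad_src + 1L))
  }
  if (!is.null(systems)) {
    bad_sys <- setdiff(unique(rec$system), systems)
    if (length(bad_sys)) {
      stop2("phenopair_validation_error", records_path,
            ": system label(s) outside vocabulary: ", toString(bad_sys))
    }
  }

  resolved <- resolve_term(graph, rec$term_id, on_unknown = "na")
  n_unknown <- sum(is.na(resolved))
  if (n_unknown > 0L && on_unknown == "fail") {
    stop2("phenopair_validation_error", records_path,
          ": unknown term id(s): ",
          toString(unique(rec$term_id[is.na(resolved)])))
  }
  n_remapped <- sum(!is.na(resolved) & resolved != rec$term_id)
  rec$term_id <- resolved
  rec <- rec[!is.na(rec$term_id), , drop = FALSE]

  key <- do.call(paste, c(rec, sep = "\r"))
  dup <- duplicated(key)
  report <- list(n_rows = length(key) + n_unknown,
                 n_kept = sum(!dup),
                 n_duplicates = sum(dup),
                 n_unknown_dropped = n_unknown,
                 n_remapped = n_remapped)
  rec <- rec[!dup, , drop = FALSE]

  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- read_table_any(meta_path, c("participant_id", "gene", "gene_group"))
    if (anyDuplicated(meta$participant_id)) {
      stop2("phenopair_validation_error", meta_path,
            ": duplicate participant_id rows")
    }
    no_grp <- meta$gene != "" & (is.na(meta$gene_group) | meta$gene_group == "")
    if (any(no_grp)) {
      stop2("phenopair_validation_error", meta_path,
            ": gene_group missing for participant(s): ",
            toString(meta$participant_id[no_grp]))
    }
  }
  new_cohort(rec, meta, report)
}

#' Write a cohort back to TSV
#'
#' @param cohort A `phenotype_cohort`.
#' @param records_path,meta_path Output TSV paths (`meta_path` may be NULL).
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, records_path, meta_path = NULL) {
  utils::write.table(cohort$records, records_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path) && !is.null(cohort$meta)) {
    utils::write.table(cohort$meta, meta_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(cohort)
}

#' Participants with data from both sources in a scope
#'
#' Participants contributing records from only one source are excluded from
#' paired analyses. For a single system the rule is: at least one record
#' from each source in that system. For `"combined"` the default (strict)
#' rule requires both sources in every system where either source reported
#' anything; the lenient rule only requires at least one record from each
#' source anywhere.
#'
#' @param cohort A `phenotype_cohort`.
#' @param scope A system label or `"combined"`.
#' @param rule `"strict"` or `"lenient"` (combined scope only).
#' @return Character vector of participant ids.
#' @export
paired_participants <- function(cohort, scope = "combined",
                                rule = c("strict", "lenient")) {
  rule <- match.arg(rule)
  rec <- cohort$records
  if (scope != "combined") {
    rec <- rec[rec$system == scope, , drop = FALSE]
    both <- tapply(rec$source, rec$participant_id,
                   function(s) all(SOURCES %in% s))
    return(sort(names(both)[unlist(both)]))
  }
  if (rule == "lenient") {
    both <- tapply(rec$source, rec$participant_id,
                   function(s) all(SOURCES %in% s))
    return(sort(names(both)[unlist(both)]))
  }
  ok <- tapply(seq_len(nrow(rec)), rec$participant_id, function(i) {
    sys <- rec$system[i]
    src <- rec$source[i]
    all(vapply(unique(sys),
               function(s) all(SOURCES %in% src[sys == s]), logical(1)))
  })
  sort(names(ok)[unlist(ok)])
}

#' Deduplicated term set for one participant, source and scope
#'
#' @inheritParams paired_participants
#' @param participant Participant id.
#' @param source `"PRD"` or `"CRD"`.
#' @return Character vector of term ids (possibly empty).
#' @export
term_set <- function(cohort, participant, source, scope = "combined") {
  rec <- cohort$records
  keep <- rec$participant_id == participant & rec$source == source
  if (scope != "combined") keep <- keep & rec$system == scope
  sort(unique(rec$term_id[keep]))
}
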