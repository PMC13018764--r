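BRANCH_SYSTEMS <- c("HP:0000478" = "vision",
                    "HP:0000707" = "neurology",
                    "HP:0025031" = "gastroenterology",
                    "HP:0002086" = "respiratory",
                    "HP:0001626" = "cardiac",
                    "HP:0000164" = "dental",
                    "HP:0002715" = "immunology",
                    "HP:0000077" = "renal",
                    "HP:0000818" = "endocrine",
                    "HP:0000598" = "ENT")

# Common childhood phenotypes that parents volunteer regardless of the
# genetic diagnosis (asthma, snoring, caries, constipation, ...).
NOISE_POOL <- c("HP:0002099", "HP:0025267", "HP:0002205", "HP:0000670",
                "HP:0002019", "HP:0002020", "HP:0002719", "HP:0012393")

#' Load the bundled mini-ontology fixture
#'
#' A hand-built ~40-term HPO subset with one branch per body system,
#' including the refraction chain (Abnormality of refraction, Myopia, Mild
#' myopia), a nystagmus sibling branch, and a seizure branch with absence
#' and focal-onset children. Used by the synthetic cohort generator and
#' throughout the test suite.
#'
#' @return An `ontology_graph` with intrinsic IC computed.
#' @export
make_fixture_ontology <- function() {
  load_obo(system.file("extdata", "mini_hpo.obo", package = "phenopair"))
}

#' Map fixture terms to body-system labels
#'
#' Assigns each phenotype term to the body system of the top-level branch
#' it sits under. The ontology root and the generic phenotypic-abnormality
#' term map to `NA`.
#'
#' @param graph An `ontology_graph` over the fixture (or any graph whose
#'   branch heads match the bundled fixture).
#' @return Named character vector term id -> system label.
#' @export
fixture_term_systems <- function(graph) {
  heads <- names(BRANCH_SYSTEMS)
  vapply(graph$ids, function(id) {
    if (id %in% heads) return(BRANCH_SYSTEMS[[id]])
    hit <- intersect(heads, graph$ancestors[[id]])
    if (length(hit)) BRANCH_SYSTEMS[[hit[[1]]]] else NA_character_
  }, character(1))
}

default_gene_table <- function() {
  data.frame(
    gene = c("CACNA1A", "STXBP1", "SCN2A", "KMT2A",
             "ARID1B", "ANKRD11", "DDX3X", "KDM5B"),
    gene_group = c("ion channel", "synaptic", "ion channel", "chromatin",
                   "chromatin", "chromatin", "RNA helicase", "chromatin"),
    profile_size = 12L,
    stringsAsFactors = FALSE)
}

#' Simulation configuration for paired-source synthetic cohorts
#'
#' Defaults encode the qualitative structure of real paired parent/clinician
#' reporting: clinicians report more specific terms (higher `specificity`
#' for CRD), parents over-report in dental, gastroenterology, immunology
#' and respiratory (higher PRD detection there), clinicians over-report in
#' neurology, and parents inject more unrelated common-childhood-phenotype
#' noise terms.
#'
#' @param seed Integer RNG seed; a fixed seed makes the cohort
#'   byte-reproducible.
#' @param n_participants Cohort size (default 200).
#' @param genes Data.frame `gene`, `gene_group`, `profile_size` describing
#'   the per-gene latent phenotype profiles.
#' @param detect 2 x n_systems matrix of per-source, per-system detection
#'   probabilities (rows `PRD`, `CRD`), or a single number applied
#'   uniformly, or `NULL` for the structured default.
#' @param specificity Named probabilities `c(PRD=, CRD=)` of reporting the
#'   exact latent term rather than an ancestor.
#' @param blur_depth Geometric success probability governing how many
#'   levels up a blurred report lands (`k = 1 + Geom(blur_depth)`,
#'   truncated at the body-system branch head).
#' @param noise_rate Named Poisson means `c(PRD=, CRD=)` of unrelated
#'   common-phenotype terms appended per participant.
#' @param latent_rate Probability each profile term enters a participant's
#'   latent phenotype set.
#' @param systems Body-system labels in play.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_participants = 200L,
                       genes = default_gene_table(), detect = NULL,
                       specificity = c(PRD = 0.6, CRD = 0.9),
                       blur_depth = 0.5,
                       noise_rate = c(PRD = 1.0, CRD = 0.3),
                       latent_rate = 0.8,
                       systems = DEFAULT_SYSTEMS) {
  if (is.null(detect)) {
    detect <- matrix(0.7, 2, length(systems),
                     dimnames = list(SOURCES, systems))
    parent_heavy <- intersect(
      c("dental", "gastroenterology", "immunology", "respiratory"), systems)
    detect["PRD", parent_heavy] <- 0.85
    detect["CRD", parent_heavy] <- 0.5
    if ("neurology" %in% systems) {
      detect["PRD", "neurology"] <- 0.6
      detect["CRD", "neurology"] <- 0.85
    }
  } else if (length(detect) == 1L && is.numeric(detect)) {
    detect <- matrix(detect, 2, length(systems),
                     dimnames = list(SOURCES, systems))
  }
  cfg <- list(seed = as.integer(seed),
              n_participants = as.integer(n_participants),
              genes = genes, detect = detect,
              specificity = specificity, blur_depth = blur_depth,
              noise_rate = noise_rate, latent_rate = latent_rate,
              systems = systems)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Symmetric null configuration (no source differences)
#'
#' Both sources share detection rate, specificity and noise rate, so any
#' per-participant category imbalance is sampling noise; used for
#' calibration of the paired tests.
#'
#' @inheritParams sim_config
#' @param detect_rate,spec,noise Shared per-source parameter values.
#' @return A `sim_config`.
#' @export
sim_config_null <- function(seed = 1L, n_participants = 120L,
                            detect_rate = 0.7, spec = 0.75, noise = 0.5) {
  sim_config(seed = seed, n_participants = n_participants,
             detect = detect_rate,
             specificity = c(PRD = spec, CRD = spec),
             noise_rate = c(PRD = noise, CRD = noise))
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1L)
  probs <- c(cfg$detect, cfg$specificity, cfg$latent_rate, cfg$blur_depth)
  if (any(probs < 0 | probs > 1)) {
    stop2("phenopair_validation_error",
          "probabilities must lie in [0, 1]")
  }
  if (any(cfg$noise_rate < 0)) {
    stop2("phenopair_validation_error", "noise_rate must be >= 0")
  }
  if (!all(c("gene", "gene_group", "profile_size") %in% names(cfg$genes))) {
    stop2("phenopair_validation_error",
          "genes table needs gene, gene_group, profile_size columns")
  }
  if (!identical(rownames(cfg$detect), SOURCES)) {
    stop2("phenopair_validation_error",
          "detect must have rows PRD, CRD")
  }
  invisible(cfg)
}

# Ancestor chain within the same body-system branch, nearest first, used
# as blur targets; a reporter never blurs past the branch head.
blur_chains <- function(graph, sysmap) {
  stats::setNames(lapply(graph$ids, function(id) {
    if (is.na(sysmap[[id]])) return(character(0))
    up <- graph$updist[[id]]
    up <- up[!is.na(sysmap[names(up)]) & sysmap[names(up)] == sysmap[[id]]]
    names(sort(up))
  }), graph$ids)
}

#' Simulate a paired-source phenotype cohort
#'
#' Generative model, per participant: a causal gene is drawn; the latent
#' phenotype set is a random subset of that gene's profile pool; each
#' source independently detects each latent term with the per-system
#' detection probability; a detected term is reported exactly with the
#' source's specificity, otherwise it is replaced by an ancestor `k`
#' levels up (`k = 1 + Geom(blur_depth)`, truncated at the branch head);
#' finally a Poisson number of unrelated common-phenotype noise terms is
#' appended per source. Ground-truth tables record the latent sets, every
#' detection/blur event and every noise injection.
#'
#' @param graph An `ontology_graph` (the bundled fixture).
#' @param config A `sim_config`.
#' @return List with `cohort` (a `phenotype_cohort`) and `truth` (list of
#'   data.frames `latent`, `reported`, `noise`, plus `profiles`).
#' @export
simulate_cohort <- function(graph, config) {
  validate_sim_config(config)
  set.seed(config$seed)
  sysmap <- fixture_term_systems(graph)
  heads <- names(BRANCH_SYSTEMS)
  # latent phenotypes are maximally specific: profiles draw from leaf
  # terms only, and sources may coarsen them via blur
  is_leaf <- lengths(graph$children[graph$ids]) == 0L
  pool <- graph$ids[is_leaf & !is.na(sysmap) & !graph$ids %in% heads &
                      sysmap[graph$ids] %in% config$systems]
  if (length(pool) == 0L) {
    stop2("phenopair_validation_error", "empty phenotype pool")
  }
  chains <- blur_chains(graph, sysmap)

  genes <- config$genes
  profiles <- stats::setNames(lapply(seq_len(nrow(genes)), function(i) {
    k <- min(genes$profile_size[i], length(pool))
    if (k == 0L) {
      stop2("phenopair_validation_error",
            "empty profile pool for gene ", genes$gene[i])
    }
    sort(sample(pool, k))
  }), genes$gene)

  n <- config$n_participants
  pids <- sprintf("P%04d", seq_len(n))
  gene_of <- sample(genes$gene, n, replace = TRUE)

  prof_len <- lengths(profiles)[gene_of]
  lat_pid <- rep(pids, prof_len)
  lat_term <- unlist(profiles[gene_of], use.names = FALSE)
  keep <- stats::runif(length(lat_term)) < config$latent_rate
  latent <- data.frame(participant_id = lat_pid[keep],
                       term_id = lat_term[keep],
                       system = unname(sysmap[lat_term[keep]]),
                       stringsAsFactors = FALSE)

  rec_list <- list(); rep_list <- list(); noise_list <- list()
  for (src in SOURCES) {
    p_det <- config$detect[src, latent$system]
    det <- stats::runif(nrow(latent)) < p_det
    d <- latent[det, , drop = FALSE]
    blur <- stats::runif(nrow(d)) >= config$specificity[[src]]
    k <- integer(nrow(d))
    k[blur] <- 1L + stats::rgeom(sum(blur), config$blur_depth)
    reported <- d$term_id
    if (any(blur)) {
      reported[blur] <- mapply(function(term, kk) {
        ch <- chains[[term]]
        if (length(ch) == 0L) term else ch[[min(kk, length(ch))]]
      }, d$term_id[blur], k[blur], USE.NAMES = FALSE)
    }
    rep_list[[src]] <- data.frame(
      participant_id = d$participant_id, source = src,
      latent_term = d$term_id, reported_term = reported,
      blurred = blur, levels_up = k, stringsAsFactors = FALSE)
    rec_list[[src]] <- data.frame(
      participant_id = d$participant_id, source = src,
      system = unname(sysmap[reported]), term_id = reported,
      stringsAsFactors = FALSE)

    n_noise <- stats::rpois(n, config$noise_rate[[src]])
    if (sum(n_noise) > 0L) {
      nz_pid <- rep(pids, n_noise)
      nz_term <- sample(NOISE_POOL, sum(n_noise), replace = TRUE)
      noise_list[[src]] <- data.frame(
        participant_id = nz_pid, source = src,
        system = unname(sysmap[nz_term]), term_id = nz_term,
        stringsAsFactors = FALSE)
    }
  }

  rec <- do.call(rbind, c(rec_list, noise_list))
  rec <- rec[order(rec$participant_id, rec$source, rec$system, rec$term_id), ,
             drop = FALSE]
  rec <- rec[!duplicated(rec), , drop = FALSE]
  rownames(rec) <- NULL

  meta <- data.frame(participant_id = pids, gene = gene_of,
                     gene_group = genes$gene_group[
                       match(gene_of, genes$gene)],
                     stringsAsFactors = FALSE)

  cohort <- new_cohort(rec, meta,
                       report = list(n_rows = nrow(rec), n_kept = nrow(rec),
                                     n_duplicates = 0L,
                                     n_unknown_dropped = 0L, n_remapped = 0L))
  truth <- list(latent = latent,
                reported = do.call(rbind, rep_list),
                noise = if (length(noise_list)) do.call(rbind, noise_list)
                        else NULL,
                profiles = profiles)
  list(cohort = cohort, truth = truth)
}

#' Replicate a simulation and run the paired category comparison
#'
#' Runs `n_reps` independent cohorts from `config` (re-seeded
#' deterministically from `config$seed`), scores each with [score_table()]
#' (similarity skipped for speed), tabulates the Parent-more/Doctor-more/
#' Equal categories for the chosen score and scopes, and applies McNemar
#' with Benjamini-Hochberg adjustment across the scope family.
#'
#' @param graph An `ontology_graph`.
#' @param config A `sim_config`.
#' @param n_reps Number of replicate cohorts.
#' @param score `"quantity"` or `"detail"`.
#' @param scopes Scopes to tabulate (default `"combined"`).
#' @param continuity Continuity correction for McNemar.
#' @param rule Pairing rule. Lenient is the default here: the generator
#'   draws systems independently, which makes the strict all-systems
#'   combined-pairing rule pathologically restrictive on synthetic
#'   cohorts (real cohorts are not system-independent).
#' @return Data.frame with one row per replicate and scope: discordant
#'   counts, statistic, raw and BH-adjusted p.
#' @export
recovery_experiment <- function(graph, config, n_reps = 100L,
                                score = c("quantity", "detail"),
                                scopes = "combined", continuity = TRUE,
                                rule = c("lenient", "strict")) {
  score <- match.arg(score)
  rule <- match.arg(rule)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- (config$seed + 104729L * r) %% 2147483629L
    sim <- simulate_cohort(graph, cfg)
    st <- score_table(sim$cohort, graph, scopes = scopes, rule = rule,
                      similarity = FALSE, detail = (score == "detail"))
    counts <- count_categories(st, score = score, by = "scope")
    res <- compare_categories(counts, family = paste0(score, ":recovery"),
                              continuity = continuity)
    out[[r]] <- data.frame(rep = r, scope = counts$group,
                           n_parent_more = counts$n_parent_more,
                           n_doctor_more = counts$n_doctor_more,
                           n_equal = counts$n_equal,
                           statistic = res$statistic, p_raw = res$p_raw,
                           p_adjusted = res$p_adjusted,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
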