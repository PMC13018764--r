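test_that("quantity_score counts distinct terms", {
  expect_equal(quantity_score(character(0)), 0L)
  expect_equal(quantity_score("HP:0000545"), 1L)
  expect_equal(quantity_score(rep(c("HP:0000545", "HP:0001250"), 3)), 2L)
  expect_equal(quantity_score(sprintf("HP:%07d", 1:6)), 6L)
})

test_that("detail_scores reproduces the worked myopia examples", {
  g <- fixture_graph()
  expect_equal(detail_scores(g, prd = "HP:0025573", crd = "HP:0000545"),
               c(prd = 1L, crd = 0L))
  expect_equal(detail_scores(g, prd = "HP:0025573", crd = "HP:0000539"),
               c(prd = 2L, crd = 0L))
  expect_equal(detail_scores(g, prd = "HP:0025573", crd = "HP:0000639"),
               c(prd = 0L, crd = 0L))
})

test_that("detail increments accumulate over all qualifying pairs", {
  g <- fixture_graph()
  # both CRD terms are ancestors of the single PRD term: 1 + 2
  expect_equal(detail_scores(g, prd = "HP:0025573",
                             crd = c("HP:0000545", "HP:0000539")),
               c(prd = 3L, crd = 0L))
  # best_pair_only caps each term at its largest increment
  expect_equal(detail_scores(g, prd = "HP:0025573",
                             crd = c("HP:0000545", "HP:0000539"),
                             best_pair_only = TRUE),
               c(prd = 2L, crd = 0L))
})

test_that("detail_scores is anti-symmetric and balanced on identical sets", {
  g <- fixture_graph()
  antichain <- function(ids) {
    # drop any term comparable to an earlier one
    keep <- character(0)
    for (t in ids) {
      if (!any(vapply(keep, function(k) {
        !is.na(ancestor_path_length(g, k, t))
      }, logical(1)))) keep <- c(keep, t)
    }
    keep
  }
  set.seed(21)
  for (i in 1:25) {
    a <- sample(g$ids, sample(1:5, 1))
    b <- sample(g$ids, sample(1:5, 1))
    d1 <- detail_scores(g, a, b)
    d2 <- detail_scores(g, b, a)
    expect_equal(unname(d1), unname(rev(d2)))
    # identical sets are always balanced (category Equal); antichains
    # (no within-set ancestor pairs) score exactly zero
    dd <- detail_scores(g, a, a)
    expect_equal(dd[["prd"]], dd[["crd"]])
    ac <- antichain(a)
    expect_equal(detail_scores(g, ac, ac), c(prd = 0L, crd = 0L))
  }
})

test_that("replacing a CRD term by its own child never decreases detail_crd", {
  g <- fixture_graph()
  set.seed(31)
  for (i in 1:25) {
    prd <- sample(g$ids, 3)
    crd <- sample(g$ids, 3)
    base <- detail_scores(g, prd, crd)[["crd"]]
    # pick a crd term with children and push it one level down
    for (t in crd) {
      kids <- setdiff(g$children[[t]], crd)   # a genuine replacement
      if (length(kids)) {
        crd2 <- c(setdiff(crd, t), kids[[1]])
        expect_gte(detail_scores(g, prd, crd2)[["crd"]], base)
        break
      }
    }
  }
})

test_that("set_similarity: identity, disjoint-branch zero, empty sentinel", {
  g <- fixture_graph()
  s <- c("HP:0000545", "HP:0001250", "HP:0002019")
  expect_equal(set_similarity(g, s, s), 1)
  expect_true(is.na(set_similarity(g, character(0), s)))
  g2 <- two_branch_graph()
  expect_equal(set_similarity(g2, "ZZ:0000004", "ZZ:0000005"), 0)
})

test_that("set_similarity equals the exhaustive pairwise oracle", {
  g <- fixture_graph()
  set.seed(41)
  for (i in 1:20) {
    a <- sample(g$ids, sample(2:4, 1))
    b <- sample(g$ids, sample(2:4, 1))
    expect_equal(set_similarity(g, a, b),
                 brute_set_sim(g$parents, g$ic, a, b), tolerance = 1e-12)
    expect_equal(set_similarity(g, a, b), set_similarity(g, b, a))
  }
})

test_that("score_table rows carry the documented categories", {
  g <- fixture_graph()
  co <- read_cohort(write_cohort_tsv(make_records(
    # P1: identical sets -> Equal / Equal / similarity 1
    list("P1", "PRD", "vision", "HP:0000545"),
    list("P1", "CRD", "vision", "HP:0000545"),
    # P2: the myopia example participant -> Parent more on detail
    list("P2", "PRD", "vision", "HP:0025573"),
    list("P2", "CRD", "vision", "HP:0000545"))), graph = g)
  st <- score_table(co, g)
  p1 <- st[st$participant_id == "P1" & st$scope == "vision", ]
  expect_equal(p1$quantity_category, "Equal")
  expect_equal(p1$detail_prd + p1$detail_crd, 0L)
  expect_equal(p1$similarity, 1)
  p2 <- st[st$participant_id == "P2" & st$scope == "vision", ]
  expect_equal(p2$detail_category, "Parent more")
  expect_equal(p2$detail_prd, 1L)
  expect_false("Doctor more" %in% p2$detail_category)
  # empty scope -> zero rows, no error
  st0 <- score_table(co, g, scopes = "renal")
  expect_equal(nrow(st0), 0L)
})

test_that("lowest_similarity ranks ascending within scope", {
  g <- fixture_graph()
  sim <- simulate_cohort(g, sim_config(seed = 9, n_participants = 40))
  st <- score_table(sim$cohort, g, rule = "lenient")
  low <- lowest_similarity(st, k = 5)
  expect_lte(nrow(low), 5L)
  expect_true(all(diff(low$similarity) >= 0))
  expect_lte(max(low$similarity),
             min(st$similarity[st$scope == "combined"], na.rm = TRUE) +
               max(st$similarity, na.rm = TRUE))
})

test_that("count_categories + compare_categories wire counts into McNemar", {
  st <- data.frame(
    participant_id = sprintf("P%d", 1:12),
    scope = "combined",
    quantity_prd = c(rep(2, 10), 1, 1),
    quantity_crd = c(rep(1, 10), 1, 2),
    detail_prd = 0L, detail_crd = 0L, similarity = NA_real_,
    quantity_category = c(rep("Parent more", 10), "Equal", "Doctor more"),
    detail_category = "Equal", stringsAsFactors = FALSE)
  class(st) <- c("score_table", "data.frame")
  counts <- count_categories(st, "quantity", "scope")
  expect_equal(counts$n_parent_more, 10L)
  expect_equal(counts$n_doctor_more, 1L)
  expect_equal(counts$n_equal, 1L)
  res <- compare_categories(counts, family = "quantity:systems")
  expect_equal(res$statistic,
               mcnemar_test(10, 1, continuity = TRUE)$statistic)
  expect_equal(res$p_adjusted, res$p_raw)  # single-member family
})
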