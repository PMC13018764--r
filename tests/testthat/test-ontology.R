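test_that("fixture loads with the refraction chain wired as documented", {
  g <- fixture_graph()
  expect_s3_class(g, "ontology_graph")
  expect_true("HP:0000539" %in% g$parents[["HP:0000545"]])
  expect_true("HP:0000545" %in% g$parents[["HP:0025573"]])
  expect_equal(g$root, "HP:0000001")
  expect_equal(unname(g$n_desc[[g$root]]), length(g$ids))
  expect_equal(unname(g$ic[[g$root]]), 0)
})

test_that("single-term ontology is valid and trivial", {
  g <- load_obo(write_obo(list("XX:0000001" = character(0))))
  expect_equal(g$root, "XX:0000001")
  expect_equal(unname(g$n_desc[["XX:0000001"]]), 1L)
  expect_equal(unname(g$ic[["XX:0000001"]]), 0)
})

test_that("load_obo rejects cycles, unknown parents and ambiguous roots", {
  expect_error(load_obo(write_obo(list(
    "XX:0000001" = character(0),
    "XX:0000002" = c("XX:0000001", "XX:0000003"),
    "XX:0000003" = "XX:0000002"))), class = "phenopair_validation_error")
  expect_error(load_obo(write_obo(list(
    "XX:0000001" = character(0),
    "XX:0000002" = "XX:0009999"))), class = "phenopair_validation_error")
  # two parentless terms: ambiguous without an explicit root, and the
  # stray one cannot reach an explicitly passed root
  p2 <- list("XX:0000001" = character(0), "XX:0000002" = character(0))
  expect_error(load_obo(write_obo(p2)), class = "phenopair_validation_error")
  expect_error(load_obo(write_obo(p2), root = "XX:0000001"),
               class = "phenopair_validation_error")
  expect_error(load_obo(write_obo(p2), root = "XX:0000009"),
               class = "phenopair_validation_error")
})

test_that("ancestor closure matches brute force on random DAGs", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    parents <- random_dag_parents(n)
    g <- load_obo(write_obo(parents))
    expect_equal(lapply(g$ancestors[names(parents)], sort),
                 brute_closure(parents))
  }
})

test_that("resolve_term handles primary, alt, replaced and unknown ids", {
  g <- fixture_graph()
  expect_equal(resolve_term(g, "HP:0000545"), "HP:0000545")
  expect_equal(resolve_term(g, "HP:9999991"), "HP:0000545")   # alt_id
  expect_equal(resolve_term(g, "HP:0008012"), "HP:0000545")   # replaced_by
  expect_error(resolve_term(g, "HP:7777777"),
               class = "phenopair_unknown_term")
  expect_equal(resolve_term(g, c("HP:0000545", "HP:7777777"),
                            on_unknown = "na"),
               c("HP:0000545", NA))
})

test_that("ancestor_path_length reproduces the myopia worked distances", {
  g <- fixture_graph()
  expect_identical(ancestor_path_length(g, "HP:0000545", "HP:0025573"), 1L)
  expect_identical(ancestor_path_length(g, "HP:0000539", "HP:0025573"), 2L)
  expect_identical(ancestor_path_length(g, "HP:0025573", "HP:0000539"), 2L)
  expect_true(is.na(ancestor_path_length(g, "HP:0000639", "HP:0025573")))
  expect_identical(ancestor_path_length(g, "HP:0000545", "HP:0000545"), 0L)
  # multi-parent term: minimum over paths (direct edge beats the 2-step one)
  expect_identical(ancestor_path_length(g, "HP:0000118", "HP:0004322"), 1L)
  expect_error(ancestor_path_length(g, "HP:7777777", "HP:0000545"),
               class = "phenopair_unknown_term")
})

test_that("path length is absent exactly when terms are unrelated", {
  g <- fixture_graph()
  set.seed(7)
  ids <- sample(g$ids, 20)
  for (a in ids) for (b in ids) {
    related <- a == b || a %in% g$ancestors[[b]] || b %in% g$ancestors[[a]]
    expect_identical(is.na(ancestor_path_length(g, a, b)), !related)
  }
})

test_that("intrinsic IC has closed form on a chain and is monotone", {
  g <- chain_graph(4)
  leaf <- g$ids[[4]]
  expect_equal(unname(g$ic[[leaf]]), -log(1 / 4))
  fg <- fixture_graph()
  for (id in fg$ids) {
    for (p in fg$parents[[id]]) {
      expect_gte(fg$ic[[id]], fg$ic[[p]])
    }
  }
})

test_that("corpus IC propagates annotations to ancestors", {
  g <- fixture_graph()
  # all annotations on one leaf: that leaf and every ancestor get ic 0
  gc <- compute_ic(g, "corpus", corpus = rep("HP:0025573", 5))
  on_path <- c("HP:0025573", g$ancestors[["HP:0025573"]])
  expect_true(all(gc$ic[on_path] == 0))
  expect_true(all(!is.finite(gc$ic[setdiff(g$ids, on_path)])))
  # monotone along edges (Inf allowed)
  for (id in gc$ids) {
    for (p in gc$parents[[id]]) expect_gte(gc$ic[[id]], gc$ic[[p]])
  }
  # resolution and warn-and-drop
  expect_warning(compute_ic(g, "corpus",
                            corpus = c("HP:0000545", "HP:7777777")),
                 "dropped 1")
  expect_error(compute_ic(g, "corpus", corpus = character(0)),
               class = "phenopair_validation_error")
})

test_that("lin_similarity matches brute force and is a bounded symmetric", {
  g <- fixture_graph()
  parents <- g$parents
  set.seed(11)
  ids <- sample(g$ids, 15)
  for (a in ids) for (b in ids) {
    s <- lin_similarity(g, a, b)
    expect_equal(s, brute_lin(parents, g$ic, a, b), tolerance = 1e-12)
    expect_equal(s, lin_similarity(g, b, a))
    expect_gte(s, 0); expect_lte(s, 1)
  }
  expect_equal(lin_similarity(g, "HP:0025573", "HP:0025573"), 1)
})

test_that("root-children pairs with only the root in common score 0", {
  g <- two_branch_graph()
  expect_equal(lin_similarity(g, "ZZ:0000004", "ZZ:0000005"), 0)
  expect_equal(lin_similarity(g, "ZZ:0000002", "ZZ:0000003"), 0)
})

test_that("descendants inverts the ancestor closure", {
  g <- fixture_graph()
  d <- descendants(g, "HP:0001250")
  expect_setequal(d, c("HP:0002121", "HP:0007359", "HP:0011153"))
  for (t in d) expect_true("HP:0001250" %in% g$ancestors[[t]])
})
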