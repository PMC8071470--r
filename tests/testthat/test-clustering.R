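make_tests_tbl <- function(ids, p) {
  tibble::tibble(set_id = ids, u_statistic = 0, p_raw = p,
                 q = p, significant = TRUE, direction = -1)
}

chain_ontology <- function() {
  # C is_a B is_a A, plus unrelated D
  ontology_graph(
    terms = tibble::tibble(id = c("A", "B", "C", "D"), name = c("a", "b", "c", "d")),
    edges = tibble::tibble(child = c("B", "C"), parent = c("A", "B"))
  )
}

test_that("significant terms cluster under their highest significant ancestor", {
  ont <- chain_ontology()
  cl <- build_clusters(make_tests_tbl(c("A", "B"), c(0.01, 0.02)), ont)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$head_term, "A")
  expect_setequal(cl$members[[1]], c("A", "B"))

  # full chain collapses into the top ancestor
  cl2 <- build_clusters(make_tests_tbl(c("A", "B", "C"), c(0.01, 0.02, 0.03)), ont)
  expect_equal(cl2$head_term, "A")
  expect_equal(cl2$n_members, 3L)

  # an intermediate significant term heads its own branch when the top is
  # not significant
  cl3 <- build_clusters(make_tests_tbl(c("B", "C"), c(0.02, 0.03)), ont)
  expect_equal(cl3$head_term, "B")

  # unrelated significant terms stay separate
  cl4 <- build_clusters(make_tests_tbl(c("A", "D"), c(0.01, 0.02)), ont)
  expect_equal(sort(cl4$head_term), c("A", "D"))
  expect_true(all(cl4$n_members == 1L))

  # ids absent from the ontology form singletons
  cl5 <- build_clusters(make_tests_tbl(c("A", "PATH_X"), c(0.01, 0.02)), ont)
  expect_true("PATH_X" %in% cl5$head_term)
})

test_that("cluster weight indices normalize to 1 and reflect member weights", {
  ont <- chain_ontology()
  cl <- build_clusters(make_tests_tbl(c("A", "D"), c(0.01, 0.01)), ont)
  expect_equal(cl$cwi, c(0.5, 0.5))
  expect_equal(sum(cl$cwi), 1, tolerance = 1e-9)

  # -log10 weights: p 1e-4 counts twice as much as p 1e-2
  cl2 <- build_clusters(make_tests_tbl(c("A", "D"), c(1e-4, 1e-2)), ont)
  expect_equal(cl2$weight[cl2$head_term == "A"], 4)
  expect_equal(cl2$cwi[cl2$head_term == "A"], 4 / 6)

  # alternative weight function
  cl3 <- build_clusters(make_tests_tbl(c("A", "D"), c(0.2, 0.6)), ont,
                        weight = "one_minus_p")
  expect_equal(cl3$weight, c(0.8, 0.4))
})

test_that("clustering partitions the significant terms regardless of input order", {
  set.seed(33)
  cfg <- synthetic_config(n_genes = 50, n_sets = 20, set_size = 5, seed = 14)
  col <- generate_collection(cfg)
  ont <- generate_ontology(col, depth = 2, n_parents = 4, seed = 14)
  tests <- make_tests_tbl(col$set_id, runif(20, 1e-6, 0.04))
  cl <- build_clusters(tests, ont)
  members <- sort(unlist(cl$members))
  expect_equal(members, sort(col$set_id))       # every term in exactly one cluster
  expect_equal(sum(cl$cwi), 1, tolerance = 1e-9)

  shuffled <- tests[sample(nrow(tests)), ]
  cl_shuf <- build_clusters(shuffled, ont)
  expect_equal(cl_shuf, cl)
})

test_that("a star ontology with a non-significant root reduces CWI to per-term p shares", {
  n <- 6
  ids <- sprintf("T%02d", seq_len(n))
  ont <- ontology_graph(
    terms = tibble::tibble(id = c("ROOT", ids), name = c("root", ids)),
    edges = tibble::tibble(child = ids, parent = "ROOT")
  )
  p <- c(1e-5, 1e-4, 1e-3, 1e-2, 0.02, 0.04)
  cl <- build_clusters(make_tests_tbl(ids, p), ont)
  expect_equal(sort(cl$head_term), ids)  # all self-headed
  expect_equal(cl$cwi[match(ids, cl$head_term)], -log10(p) / sum(-log10(p)))
})

test_that("rank_clusters orders by CWI with the stated tie-breaks", {
  cl <- build_clusters(
    make_tests_tbl(c("A", "D"), c(0.01, 0.02)), chain_ontology()
  )
  ranked <- rank_clusters(cl)
  expect_equal(ranked$rank, 1:2)
  expect_true(all(diff(ranked$cwi) <= 0))
  # equal p gives equal weight: tie broken by head p then id
  cl_tie <- build_clusters(make_tests_tbl(c("A", "D"), c(0.02, 0.02)), chain_ontology())
  ranked_tie <- rank_clusters(cl_tie)
  expect_equal(ranked_tie$head_term, c("A", "D"))

  single <- build_clusters(make_tests_tbl("A", 0.01), chain_ontology())
  rs <- rank_clusters(single)
  expect_equal(rs$rank, 1L)
  expect_equal(rs$cwi, 1)
})

test_that("common top terms intersect group lists and order by mean rank", {
  groups <- list(g1 = c("X", "Y", "Z"), g2 = c("X", "Y", "W"), g3 = c("Y", "X", "V"))
  tab <- common_top_terms(groups, k = 3)
  # X ranks 1/1/2, Y ranks 2/2/1
  expect_equal(tab$term, c("X", "Y"))
  expect_equal(tab$mean_rank, c(4 / 3, 5 / 3))
  expect_equal(tab$rank_g3, c(2L, 1L))

  same <- common_top_terms(list(a = c("P", "Q", "R"), b = c("P", "Q", "R")), k = 3)
  expect_equal(same$term, c("P", "Q", "R"))

  disjoint <- common_top_terms(list(a = c("P"), b = c("Q")), k = 1)
  expect_equal(nrow(disjoint), 0L)

  expect_error(common_top_terms(list(c("A"))), class = "gsreg_input_error")
})

test_that("categorize_terms partitions with unmapped terms falling into others", {
  tab <- tibble::tibble(order = 1:3, term = c("X", "Y", "Z"))
  out <- categorize_terms(tab, c(X = "immune", Y = "metabolism"))
  expect_equal(out$category[out$term == "Z"], "others")
  expect_equal(sort(unique(out$category)), c("immune", "metabolism", "others"))

  all_others <- categorize_terms(tab, character(0))
  expect_true(all(all_others$category == "others"))

  one <- categorize_terms(tab, c(Y = "solo"))
  expect_equal(sum(one$category == "solo"), 1L)
})

test_that("the packaged borderline-tumour reference tables carry the expected category structure", {
  terms <- bot_common_go_terms()
  expect_equal(nrow(terms), 41L)
  counts <- table(terms$category)
  expect_equal(unname(counts["immune_inflammatory"]), 3L)
  expect_equal(unname(counts["membrane_transporter"]), 9L)
  expect_equal(unname(counts["cycle_signaling"]), 16L)
  expect_equal(unname(counts["metabolism"]), 9L)
  expect_equal(unname(counts["others"]), 4L)

  # categorize_terms with the packaged map reproduces the partition
  out <- categorize_terms(terms[, c("order", "term")],
                          setNames(terms$category, terms$term))
  expect_equal(table(out$category), counts)
})
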