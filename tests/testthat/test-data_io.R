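test_that("read_gmt parses lines, de-duplicates genes and enforces format", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO_X\tdesc\tA\tB\tC", "GO_Y\tother\tA\tA\tB"), path)
  col <- read_gmt(path)
  expect_s3_class(col, "gene_set_collection")
  expect_equal(nrow(col), 2L)
  expect_equal(col$genes[[1]], c("A", "B", "C"))
  expect_equal(col$genes[[2]], c("A", "B"))  # duplicates dropped, first kept

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO_X\tdesc\tA", "GO_Y\tonly_two_fields"), bad)
  expect_error(read_gmt(bad), "line 2")

  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO_X\td\tA\tB", "GO_X\td\tC\tD"), dup)
  expect_error(read_gmt(dup), "unique")
})

test_that("gmt writer round-trips a collection bit-exactly", {
  col <- gene_set_collection(
    set_id = c("S1", "S2"), name = c("first", "second"),
    genes = list(c("TP53", "EGFR"), c("BRCA1", "BRCA2", "ATM"))
  )
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(col, path)
  back <- read_gmt(path)
  expect_equal(back$set_id, col$set_id)
  expect_equal(back$name, col$name)
  expect_equal(back$genes, col$genes)
  # and the serialized bytes are stable across a second round-trip
  path2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("expression tables load with labels, collapsing duplicate gene rows by max", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2",
               "TP53\t5\t1",
               "EGFR\t2\t2",
               "TP53\t9\t0.5",
               "MYC\t1\t3"), path)
  x <- read_expression_table(path, c(s1 = "case", s2 = "control"))
  expect_equal(dim(x), c(3L, 2L))
  expect_equal(x$values["TP53", ], c(s1 = 9, s2 = 1))  # per-sample max
  expect_equal(unname(x$group), c("case", "control"))
})

test_that("malformed expression tables fail with located errors", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "TP53\t5\toops"), bad)
  expect_error(read_expression_table(bad, c(s1 = "case", s2 = "control")),
               "row 1.*column 's2'")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\ts1", empty)
  expect_error(read_expression_table(empty, c(s1 = "case")), "empty")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "TP53\t1\t2"), path)
  expect_error(read_expression_table(path, c(s1 = "case")), "missing from labels")
})

test_that("obo parsing keeps is_a edges, drops obsolete terms, walks ancestors", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:A", "name: root", "",
               "[Term]", "id: GO:B", "name: middle", "is_a: GO:A ! root", "",
               "[Term]", "id: GO:C", "name: leaf", "is_a: GO:B", "",
               "[Term]", "id: GO:OLD", "name: gone", "is_obsolete: true", ""), path)
  g <- read_obo(path)
  expect_equal(sort(g$terms$id), c("GO:A", "GO:B", "GO:C"))
  expect_false("GO:OLD" %in% g$terms$id)
  expect_setequal(ontology_ancestors(g, "GO:C"), c("GO:A", "GO:B"))
  expect_equal(ontology_ancestors(g, "GO:A"), character(0))
})

test_that("cyclic is_a relations are rejected", {
  expect_error(
    ontology_graph(
      terms = tibble::tibble(id = c("A", "B"), name = c("a", "b")),
      edges = tibble::tibble(child = c("A", "B"), parent = c("B", "A"))
    ),
    class = "gsreg_cycle_error"
  )
})

test_that("harmonize intersects genes, concatenates samples, errors on disjoint inputs", {
  m1 <- make_matrix(list(s1 = c(A = 1, B = 2, C = 3)), "control")
  m2 <- make_matrix(list(s2 = c(B = 5, C = 1, D = 2)), "case")
  merged <- harmonize(list(m1, m2))
  expect_setequal(rownames(merged$values), c("B", "C"))
  expect_equal(ncol(merged$values), 2L)
  expect_equal(unname(merged$group), c("control", "case"))

  # identity on a single matrix
  solo <- harmonize(list(m1))
  expect_equal(solo$values, m1$values)

  m3 <- make_matrix(list(s3 = c(X = 1, Y = 2)), "case")
  expect_error(harmonize(list(m1, m3)), class = "gsreg_harmonize_error")
})

test_that("per-platform positive rescaling before harmonization leaves the functionome unchanged", {
  set.seed(42)
  genes <- paste0("G", 1:20)
  vals1 <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(genes, paste0("a", 1:6)))
  vals2 <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(genes, paste0("b", 1:4)))
  g1 <- rep(c("control", "case"), each = 3)
  g2 <- rep(c("control", "case"), each = 2)
  col <- gene_set_collection(paste0("S", 1:5), genes = replicate(5, sample(genes, 6), simplify = FALSE))

  f_ref <- build_functionome(
    harmonize(list(expression_matrix(vals1, g1), expression_matrix(vals2, g2))), col)
  f_scaled <- build_functionome(
    harmonize(list(expression_matrix(vals1 * 1000, g1), expression_matrix(vals2, g2))), col)
  expect_equal(f_scaled$gsr, f_ref$gsr)
})
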