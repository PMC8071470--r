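test_that("pair order bits encode within-sample orderings with the stated tie rule", {
  vals <- c(A = 1, B = 2, C = 3)
  po <- pair_orders(vals, c("A", "B", "C"), set_id = "s")
  expect_equal(po$bits, c(1L, 1L, 1L))  # fully increasing

  expect_equal(pair_orders(c(A = 3, B = 2, C = 1), c("A", "B", "C"))$bits, c(0L, 0L, 0L))
  expect_equal(pair_orders(c(A = 1, B = 3, C = 2), c("A", "B", "C"))$bits, c(1L, 1L, 0L))

  # exact ties resolve by ascending gene symbol, so A < B and the result is
  # deterministic
  tied <- pair_orders(c(A = 5, B = 5), c("A", "B"))
  expect_equal(tied$bits, 1L)
  tied_rev <- pair_orders(c(A = 5, B = 5), c("B", "A"))
  expect_equal(tied_rev$bits, 0L)  # pair listed (B, A): B < A is false

  expect_error(pair_orders(c(A = 1), c("A", "ZZZ")), class = "gsreg_unretained_error")
})

test_that("rank templates take the majority control ordering, support 0.5 voting 1", {
  ctl <- abc_controls()
  tpl <- build_template(ctl, c("A", "B", "C"), set_id = "s")
  expect_equal(tpl$template_bits, c(1L, 1L, 1L))
  expect_equal(tpl$support, c(1, 1, 1))

  # one control flips A/B: support 2/3 keeps the majority bit
  ctl2 <- make_matrix(
    list(c1 = c(A = 1, B = 2, C = 3), c2 = c(A = 1, B = 2, C = 3),
         c3 = c(A = 2, B = 1, C = 3)),
    rep("control", 3)
  )
  tpl2 <- build_template(ctl2, c("A", "B", "C"))
  expect_equal(tpl2$template_bits, c(1L, 1L, 1L))
  expect_equal(tpl2$support[1], 2 / 3)

  # even split on pair (A,B): support exactly 0.5 votes 1
  ctl3 <- make_matrix(
    list(c1 = c(A = 1, B = 2), c2 = c(A = 2, B = 1)), rep("control", 2)
  )
  tpl3 <- build_template(ctl3, c("A", "B"))
  expect_equal(tpl3$support, 0.5)
  expect_equal(tpl3$template_bits, 1L)

  expect_error(build_template(matrix(1, 2, 0, dimnames = list(c("A", "B"), NULL)),
                              c("A", "B")),
               class = "gsreg_input_error")
})

test_that("the GSR index is the fraction of template-matching pairs", {
  ctl <- abc_controls()
  tpl <- build_template(ctl, c("A", "B", "C"), set_id = "s")

  same <- pair_orders(c(A = 1, B = 2, C = 3), c("A", "B", "C"), set_id = "s")
  expect_identical(gsr_index(same, tpl), 1)

  opposite <- pair_orders(c(A = 3, B = 2, C = 1), c("A", "B", "C"), set_id = "s")
  expect_identical(gsr_index(opposite, tpl), 0)

  partial <- pair_orders(c(A = 1, B = 3, C = 2), c("A", "B", "C"), set_id = "s")
  expect_equal(gsr_index(partial, tpl), 2 / 3)

  other <- pair_orders(c(A = 1, B = 2, C = 3), c("A", "B", "C"), set_id = "other")
  expect_error(gsr_index(other, tpl), class = "gsreg_input_error")
})

test_that("gsr_index agrees with a brute-force pair-enumeration oracle", {
  set.seed(101)
  for (trial in 1:300) {
    m <- sample(2:5, 1)
    nc <- sample(1:6, 1)
    genes <- sample(LETTERS, m)
    ctl_vals <- matrix(sample(1:8, m * nc, replace = TRUE), m, nc,
                       dimnames = list(genes, paste0("c", seq_len(nc))))
    sample_vals <- setNames(sample(1:8, m, replace = TRUE), genes)

    tpl <- build_template(ctl_vals, genes, set_id = "s")
    po <- pair_orders(sample_vals, genes, set_id = "s")
    expect_equal(gsr_index(po, tpl), brute_gsr(ctl_vals, sample_vals, genes))
  }
})

test_that("the functionome is invariant to strictly increasing per-sample transforms", {
  set.seed(7)
  genes <- paste0("G", 1:30)
  vals <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(genes, paste0("s", 1:8)))
  group <- rep(c("control", "case"), each = 4)
  col <- gene_set_collection(paste0("S", 1:6),
                             genes = replicate(6, sample(genes, 5), simplify = FALSE))
  f_ref <- build_functionome(expression_matrix(vals, group), col)

  transforms <- list(function(v) exp(v), function(v) v^3, function(v) 100 * v + 5,
                     function(v) atan(v), function(v) rank(v))
  for (trial in 1:10) {
    vals2 <- vals
    for (j in seq_len(ncol(vals2))) {
      vals2[, j] <- transforms[[sample(length(transforms), 1)]](vals2[, j])
    }
    f_new <- build_functionome(expression_matrix(vals2, group), col)
    expect_equal(f_new$gsr, f_ref$gsr)
  }
})

test_that("complementing a sample's pair bits reflects the GSR index around 1", {
  ctl <- abc_controls()
  tpl <- build_template(ctl, c("A", "B", "C"), set_id = "s")
  po <- pair_orders(c(A = 1, B = 3, C = 2), c("A", "B", "C"), set_id = "s")
  flipped <- po
  flipped$bits <- 1L - po$bits
  expect_equal(gsr_index(flipped, tpl), 1 - gsr_index(po, tpl))
})

test_that("gene order within a set definition does not change the GSR index", {
  set.seed(11)
  genes <- paste0("G", 1:10)
  vals <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(genes, paste0("s", 1:5)))
  x <- expression_matrix(vals, c("control", "control", "control", "case", "case"))
  for (trial in 1:20) {
    sel <- sample(genes, 4)
    f1 <- build_functionome(x, gene_set_collection("S", genes = list(sel)))
    f2 <- build_functionome(x, gene_set_collection("S", genes = list(sample(sel))))
    expect_equal(f1$gsr, f2$gsr)
  }
})

test_that("a single control scores 1 against its own template; skip log records short sets", {
  x <- make_matrix(list(c1 = c(A = 3, B = 1, C = 2)), "control")
  col <- gene_set_collection(c("S1", "S2"), genes = list(c("A", "B", "C"), c("A", "MISSING")))
  f <- build_functionome(x, col)
  expect_equal(unname(f$gsr["c1", "S1"]), 1)
  expect_equal(f$skipped$set_id, "S2")
  expect_equal(f$skipped$n_measured_genes, 1L)
  expect_false("S2" %in% colnames(f$gsr))

  only_short <- gene_set_collection("S2", genes = list(c("A", "MISSING")))
  expect_error(build_functionome(x, only_short), "no gene set retained")
})

test_that("leave-one-out control scoring drops self-inclusive bias for odd control counts", {
  set.seed(3)
  genes <- paste0("G", 1:6)
  vals <- matrix(rnorm(6 * 7), 6, 7, dimnames = list(genes, paste0("s", 1:7)))
  x <- expression_matrix(vals, c(rep("control", 5), "case", "case"))
  col <- gene_set_collection("S", genes = list(genes))
  f_in <- build_functionome(x, col)
  f_loo <- build_functionome(x, col, leave_one_out = TRUE)
  ctrl <- paste0("s", 1:5)
  # cases are scored identically; controls can only score lower without
  # their own vote in the template (majority over an even count can shift,
  # but never in the self-favouring direction)
  expect_equal(f_in$gsr[c("s6", "s7"), ], f_loo$gsr[c("s6", "s7"), ])
  expect_true(mean(f_loo$gsr[ctrl, ]) <= mean(f_in$gsr[ctrl, ]) + 1e-12)

  one_ctl <- expression_matrix(vals[, 1:2], c("control", "case"))
  expect_error(build_functionome(one_ctl, col, leave_one_out = TRUE),
               class = "gsreg_input_error")
})

test_that("corrected group means summarize the functionome entries", {
  f <- structure(
    list(gsr = matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2,
                      dimnames = list(c("a", "b"), c("S1", "S2"))),
         group = c(a = "case", b = "case"),
         subtype = c(a = NA_character_, b = NA_character_),
         skipped = tibble::tibble()),
    class = "functionome"
  )
  res <- corrected_group_mean(f, "case")
  expect_equal(res$mean, 0.5)
  expect_equal(res$sd, sd(c(0.2, 0.6, 0.4, 0.8)))
  expect_error(corrected_group_mean(f, "control"), class = "gsreg_input_error")

  ones <- f
  ones$gsr[] <- 1
  res1 <- corrected_group_mean(ones, "case")
  expect_equal(res1$mean, 1)
  expect_equal(res1$sd, 0)
})
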