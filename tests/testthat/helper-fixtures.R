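# Shared fixtures and independent oracles for the test suite.

# Small expression matrix: genes x samples from a named list of sample
# value vectors; all vectors must share the gene names of the first.
make_matrix <- function(samples, group, genes = NULL) {
  genes <- genes %||% names(samples[[1]])
  values <- vapply(samples, function(s) unname(s[genes]), numeric(length(genes)))
  rownames(values) <- genes
  expression_matrix(values, group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Three controls all ordered A < B < C, used by the definitional anchors.
abc_controls <- function() {
  make_matrix(
    list(c1 = c(A = 1, B = 2, C = 3),
         c2 = c(A = 2, B = 5, C = 9),
         c3 = c(A = 0.1, B = 0.2, C = 0.7)),
    group = c("control", "control", "control")
  )
}

# --- independent oracles ----------------------------------------------------

# Brute-force GSR: naive loops over all gene pairs, majority vote over
# controls, match count for the sample. Deliberately written without any of
# the package's vectorized internals.
brute_gsr <- function(control_values, sample_values, set_genes) {
  set_genes <- unique(set_genes)
  set_genes <- set_genes[set_genes %in% rownames(control_values)]
  stopifnot(length(set_genes) >= 2)
  lex <- function(g) match(g, sort(unique(set_genes), method = "radix"))
  lt <- function(vi, vj, gi, gj) (vi < vj) || (vi == vj && lex(gi) < lex(gj))
  matches <- 0L; total <- 0L
  for (i in seq_along(set_genes)) {
    for (j in seq_along(set_genes)) {
      if (i >= j) next
      gi <- set_genes[i]; gj <- set_genes[j]
      votes <- 0L
      for (s in seq_len(ncol(control_values))) {
        if (lt(control_values[gi, s], control_values[gj, s], gi, gj)) votes <- votes + 1L
      }
      template_bit <- as.integer(votes / ncol(control_values) >= 0.5)
      sample_bit <- as.integer(lt(sample_values[gi], sample_values[gj], gi, gj))
      matches <- matches + as.integer(sample_bit == template_bit)
      total <- total + 1L
    }
  }
  matches / total
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enum_p <- function(case, control) {
  pooled <- c(case, control)
  m <- length(case); n <- length(control)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(case, control)
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  p_lo <- mean(u_all <= u_obs + eps)
  p_hi <- mean(u_all >= u_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

# Inversion count of a permutation (Kendall distance from identity).
count_inversions <- function(perm) {
  sum(outer(seq_along(perm), seq_along(perm), "<") & outer(perm, perm, ">"))
}
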