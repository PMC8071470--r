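#' Pairwise order encoding of one sample over a gene set
#'
#' The ordinal encoding at the heart of the gene set regularity (GSR) index,
#' in the spirit of differential rank conservation (DIRAC): for the genes of
#' a set that are measured in the data, every pair (i, j) with i before j in
#' the set's measured-gene ordering contributes one bit, 1 when gene i is
#' expressed below gene j in this sample and 0 otherwise. Comparisons are
#' strict; exact expression ties are broken deterministically by ascending
#' gene-symbol order (byte-wise, locale independent), so the encoding is a
#' total order and reproducible across machines.
#'
#' @param sample_values Named numeric vector: expression of one sample, names
#'   are gene symbols (the gene universe of the matrix).
#' @param gene_set Character vector of the set's gene symbols, or one row of
#'   a [gene_set_collection()] supplied as a list with `set_id`/`genes`.
#' @param set_id Identifier recorded on the result.
#' @return An object of class `pair_order`: list with `set_id`, `genes`
#'   (the measured genes in set order), `pairs` (2-column character matrix)
#'   and `bits` (integer 0/1 vector of length m(m-1)/2).
#' @export
pair_orders <- function(sample_values, gene_set, set_id = "set") {
  genes <- measured_set_genes(gene_set, names(sample_values))
  if (length(genes) < 2L) {
    stop_gsreg("gene set has fewer than 2 measured genes; set is unretained", "gsreg_unretained_error")
  }
  bits <- pair_bits_matrix(matrix(sample_values[genes], ncol = 1,
                                  dimnames = list(genes, "s")), genes)
  idx <- combn(length(genes), 2L)
  structure(
    list(set_id = set_id, genes = genes,
         pairs = cbind(genes[idx[1L, ]], genes[idx[2L, ]]),
         bits = as.integer(bits[, 1L])),
    class = "pair_order"
  )
}

# Genes of a set that are present in the measured universe, in set order.
measured_set_genes <- function(gene_set, universe) {
  if (is.list(gene_set) && !is.null(gene_set$genes)) gene_set <- gene_set$genes
  gene_set <- unique(as.character(gene_set))
  gene_set[gene_set %in% universe]
}

# Bit matrix (n_pairs x n_samples) of strict pairwise orderings for the
# given genes over all columns of `values`. Ties broken by gene-symbol rank.
pair_bits_matrix <- function(values, genes) {
  m <- length(genes)
  idx <- combn(m, 2L)
  vi <- values[genes[idx[1L, ]], , drop = FALSE]
  vj <- values[genes[idx[2L, ]], , drop = FALSE]
  lr <- lex_rank(genes)
  tie_break <- lr[idx[1L, ]] < lr[idx[2L, ]]
  bits <- (vi < vj) | ((vi == vj) & tie_break)
  storage.mode(bits) <- "integer"
  bits
}

#' Control-group rank template for a gene set
#'
#' The majority pair-order pattern across control samples: for every gene
#' pair the template bit is the majority vote of the controls' pair-order
#' bits, the package's rendering of the most common gene expression ordering
#' in the normal group. `support` records the fraction of controls voting 1;
#' at an exact 0.5 split the template bit is 1 by convention (the choice only
#' relabels matched/unmatched symmetrically).
#'
#' @param controls An `expr_matrix` whose control samples are used (case
#'   columns, if present, are ignored), or a plain genes-by-samples numeric
#'   matrix of control samples.
#' @param gene_set Character vector of gene symbols (or list with `genes`).
#' @param set_id Identifier recorded on the result.
#' @return Object of class `rank_template`: list with `set_id`, `genes`,
#'   `pairs`, `template_bits` (0/1 integer) and `support` (in \[0, 1\]).
#' @export
build_template <- function(controls, gene_set, set_id = "set") {
  values <- control_values(controls)
  if (ncol(values) == 0L) {
    stop_gsreg("no control samples available to build a rank template", "gsreg_input_error")
  }
  genes <- measured_set_genes(gene_set, rownames(values))
  if (length(genes) < 2L) {
    stop_gsreg("gene set has fewer than 2 measured genes; set is unretained", "gsreg_unretained_error")
  }
  bits <- pair_bits_matrix(values, genes)
  support <- unname(rowMeans(bits))
  idx <- combn(length(genes), 2L)
  structure(
    list(set_id = set_id, genes = genes,
         pairs = cbind(genes[idx[1L, ]], genes[idx[2L, ]]),
         template_bits = as.integer(support >= 0.5),
         support = support),
    class = "rank_template"
  )
}

control_values <- function(x) {
  if (inherits(x, "expr_matrix")) {
    return(x$values[, x$group == "control", drop = FALSE])
  }
  stopifnot(is.matrix(x), is.numeric(x))
  x
}

#' Gene set regularity index of one sample
#'
#' The fraction of gene pairs whose ordering in the sample matches the
#' control rank template. Ranges from 0 to 1: 1 means the regularity of the
#' gene set is unchanged relative to the normal state, 0 means the sample is
#' oppositely ordered on every pair, the maximally dysregulated state.
#'
#' @param sample A [pair_orders()] encoding.
#' @param template A [build_template()] result for the same set.
#' @return A single number in \[0, 1\].
#' @export
gsr_index <- function(sample, template) {
  stopifnot(inherits(sample, "pair_order"), inherits(template, "rank_template"))
  if (!identical(sample$set_id, template$set_id) ||
      !identical(sample$pairs, template$pairs)) {
    stop_gsreg("sample and template disagree on set id or pair list", "gsreg_input_error")
  }
  mean(sample$bits == template$template_bits)
}

#' Build the functionome of a cohort
#'
#' For every retained gene set (at least two genes measured in the matrix),
#' builds the control rank template and scores every sample — cases and
#' controls alike — against it, assembling the samples-by-sets matrix of GSR
#' indices that quantifies each sample's global functional regularity. By
#' default controls are scored against the template they all contributed to
#' (self-inclusive), which leaves heterogeneous control groups with means
#' below 1; `leave_one_out = TRUE` instead scores each control against the
#' template of the remaining controls.
#'
#' Sets dropped for having fewer than two measured genes are recorded in the
#' `skipped` element rather than raising an error, so silent filtering stays
#' auditable.
#'
#' @param x An `expr_matrix` with at least one control sample.
#' @param collection A [gene_set_collection()].
#' @param leave_one_out Score controls against templates excluding
#'   themselves. Requires at least two controls.
#' @return Object of class `functionome`: list with `gsr` (samples x sets
#'   numeric matrix, entries in \[0, 1\]), `group`, `subtype` (per-sample,
#'   as in `x`) and `skipped` (tibble `set_id`, `n_measured_genes`,
#'   `reason`).
#' @export
build_functionome <- function(x, collection, leave_one_out = FALSE) {
  stopifnot(inherits(x, "expr_matrix"), inherits(collection, "gene_set_collection"))
  ctrl <- which(x$group == "control")
  if (length(ctrl) == 0L) {
    stop_gsreg("cohort has no control samples", "gsreg_input_error")
  }
  if (leave_one_out && length(ctrl) < 2L) {
    stop_gsreg("leave-one-out scoring needs at least two controls", "gsreg_input_error")
  }
  genes_universe <- rownames(x$values)
  n <- ncol(x$values)
  kept <- logical(nrow(collection))
  skipped <- list()
  cols <- list()
  for (k in seq_len(nrow(collection))) {
    genes <- measured_set_genes(collection$genes[[k]], genes_universe)
    m <- length(genes)
    if (m < 2L) {
      skipped[[length(skipped) + 1L]] <- tibble(
        set_id = collection$set_id[k], n_measured_genes = m,
        reason = "fewer than 2 measured genes"
      )
      next
    }
    kept[k] <- TRUE
    bits <- pair_bits_matrix(x$values, genes)
    support <- rowMeans(bits[, ctrl, drop = FALSE])
    tmpl <- support >= 0.5
    gsr <- colMeans(bits == tmpl)
    if (leave_one_out) {
      nc <- length(ctrl)
      ctrl_sum <- rowSums(bits[, ctrl, drop = FALSE])
      for (j in seq_along(ctrl)) {
        supp_j <- (ctrl_sum - bits[, ctrl[j]]) / (nc - 1L)
        gsr[ctrl[j]] <- mean(bits[, ctrl[j]] == (supp_j >= 0.5))
      }
    }
    cols[[collection$set_id[k]]] <- gsr
  }
  if (length(cols) == 0L) {
    stop_gsreg("no gene set retained: none has 2 or more measured genes", "gsreg_input_error")
  }
  gsr <- do.call(cbind, cols)
  rownames(gsr) <- colnames(x$values)
  structure(
    list(gsr = gsr, group = x$group, subtype = x$subtype,
         skipped = if (length(skipped)) bind_rows(skipped) else
           tibble(set_id = character(), n_measured_genes = integer(), reason = character())),
    class = "functionome"
  )
}

#' @export
print.functionome <- function(x, ...) {
  cat(sprintf(
    "<functionome> %d samples x %d gene sets (GSR in [%.3f, %.3f]); %d sets skipped\n",
    nrow(x$gsr), ncol(x$gsr), min(x$gsr), max(x$gsr), nrow(x$skipped)
  ))
  invisible(x)
}

#' @describeIn build_functionome Long-format view with columns `sample`,
#'   `set_id`, `gsr`, `group`.
#' @param ... Ignored.
#' @export
as_tibble.functionome <- function(x, ...) {
  tibble(
    sample = rep(rownames(x$gsr), times = ncol(x$gsr)),
    set_id = rep(colnames(x$gsr), each = nrow(x$gsr)),
    gsr = as.vector(x$gsr),
    group = rep(unname(x$group), times = ncol(x$gsr))
  )
}

#' @export
tidy.functionome <- function(x, ...) as_tibble(x)

#' Group mean and spread of functionome GSR indices
#'
#' Pools every GSR entry of the requested group's samples and reports the
#' mean and standard deviation — the per-cohort summary conventionally shown
#' next to the control group's own mean, which it is read against (a case
#' mean well below the control mean indicates global loss of regularity).
#'
#' @param f A [build_functionome()] result.
#' @param group Character: group labels (`"case"`, `"control"`) and/or
#'   explicit sample ids.
#' @return A tibble with columns `group`, `mean`, `sd`, `n_samples`,
#'   `n_sets`.
#' @export
corrected_group_mean <- function(f, group = c("case", "control")) {
  stopifnot(inherits(f, "functionome"))
  purrr::map_dfr(group, function(g) {
    rows <- if (g %in% c("case", "control")) which(f$group == g) else which(rownames(f$gsr) %in% g)
    if (length(rows) == 0L) {
      stop_gsreg(sprintf("no samples in group '%s'", g), "gsreg_input_error")
    }
    vals <- f$gsr[rows, , drop = FALSE]
    tibble(group = g, mean = mean(vals), sd = sd(as.vector(vals)),
           n_samples = length(rows), n_sets = ncol(vals))
  })
}

#' @describeIn build_functionome Write the functionome as TSV (rows =
#'   samples, columns = gene set ids) plus, optionally, the skip log.
#' @param f A `functionome`.
#' @param path Output TSV path.
#' @param skip_path Optional path for the skip log TSV.
#' @export
write_functionome <- function(f, path, skip_path = NULL) {
  stopifnot(inherits(f, "functionome"))
  tab <- as.data.frame(f$gsr)
  tab <- cbind(sample_id = rownames(f$gsr), group = unname(f$group), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(skip_path)) readr::write_tsv(f$skipped, skip_path, progress = FALSE)
  invisible(f)
}

#' Histogram view of a functionome
#'
#' Side-by-side distribution of case and control GSR indices over equal
#' width bins of \[0, 1\]; a left-shifted or bimodal case distribution is
#' the visual signature of widespread dysregulation.
#'
#' @param object A `functionome`.
#' @param n_bins Number of bins.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.functionome <- function(object, n_bins = 50, ...) {
  dat <- as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gsr, fill = .data$group)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, length.out = n_bins + 1L),
                            position = "identity", alpha = 0.55) +
    ggplot2::scale_fill_manual(values = c(case = "#E69F00", control = "#56B4E9")) +
    ggplot2::labs(x = "GSR index", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}
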