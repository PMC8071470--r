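#' Construct an expression matrix with sample annotations
#'
#' The basic input container of the pipeline: a genes-by-samples numeric
#' matrix with a case/control label per sample, plus optional free-text
#' subtype and platform annotations. Values may be on any platform-specific
#' scale; all downstream gene set regularity computations are ordinal within
#' each sample, so no cross-sample normalization is required or performed.
#'
#' @param values Numeric matrix, genes in rows (unique rownames = gene
#'   symbols), samples in columns (unique colnames = sample ids). Missing
#'   values are not allowed.
#' @param group Character vector of `"case"`/`"control"`, one per sample.
#'   May be named by sample id; otherwise taken in column order.
#' @param subtype Optional character vector of case subtype labels (e.g.
#'   `"serous"`, `"mucinous"`), one per sample; `NA` for controls.
#' @param platform Optional character vector of platform identifiers, one
#'   per sample.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `group`, `subtype` and `platform` (the latter three named by sample id).
#' @export
expression_matrix <- function(values, group, subtype = NULL, platform = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_gsreg("`values` must be a numeric matrix (genes x samples)", "gsreg_input_error")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop_gsreg("expression matrix has no data", "gsreg_input_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_gsreg("expression matrix needs gene rownames and sample colnames", "gsreg_input_error")
  }
  if (anyDuplicated(rownames(values))) {
    stop_gsreg("duplicate gene symbols in expression matrix", "gsreg_input_error")
  }
  if (anyDuplicated(colnames(values))) {
    stop_gsreg("duplicate sample ids in expression matrix", "gsreg_input_error")
  }
  if (anyNA(values)) {
    stop_gsreg("expression matrix contains missing values", "gsreg_input_error")
  }
  samples <- colnames(values)
  group <- align_annotation(group, samples, "group")
  if (anyNA(group) || !all(group %in% c("case", "control"))) {
    stop_gsreg("every sample needs a group label of 'case' or 'control'", "gsreg_input_error")
  }
  subtype <- if (is.null(subtype)) setNames(rep(NA_character_, length(samples)), samples) else align_annotation(subtype, samples, "subtype")
  platform <- if (is.null(platform)) setNames(rep(NA_character_, length(samples)), samples) else align_annotation(platform, samples, "platform")
  structure(
    list(values = values, group = group, subtype = subtype, platform = platform),
    class = "expr_matrix"
  )
}

align_annotation <- function(x, samples, what) {
  x <- as.character(x)
  if (!is.null(names(x))) {
    missing <- setdiff(samples, names(x))
    if (length(missing) > 0L) {
      stop_gsreg(
        sprintf("samples missing from %s labels: %s", what, paste(missing, collapse = ", ")),
        "gsreg_input_error"
      )
    }
    return(setNames(x[samples], samples))
  }
  if (length(x) != length(samples)) {
    stop_gsreg(sprintf("`%s` must have one entry per sample", what), "gsreg_input_error")
  }
  setNames(x, samples)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples (%d case, %d control)\n",
    nrow(x$values), ncol(x$values),
    sum(x$group == "case"), sum(x$group == "control")
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @describeIn expression_matrix Long-format view: one row per
#'   gene-sample pair with columns `gene`, `sample`, `value`, `group`.
#' @param x An `expr_matrix`.
#' @param ... Ignored.
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    group = rep(unname(x$group), each = nrow(x$values))
  )
}

#' Read a sample label table
#'
#' Two-to-four column tab-separated file: `sample_id`, `group`
#' (case/control), and optionally `subtype` and `platform`.
#'
#' @param path Path to the labels TSV.
#' @return A tibble with columns `sample_id`, `group`, `subtype`, `platform`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    stop_gsreg(sprintf("labels file not found: %s", path), "gsreg_io_error")
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(tab))) {
    stop_gsreg("labels file needs columns 'sample_id' and 'group'", "gsreg_io_error")
  }
  if (!"subtype" %in% names(tab)) tab$subtype <- NA_character_
  if (!"platform" %in% names(tab)) tab$platform <- NA_character_
  tab[, c("sample_id", "group", "subtype", "platform")]
}

#' Read a genes-by-samples expression table
#'
#' Tab-separated table with gene symbols in the first column and one column
#' per sample; every data cell must be numeric and non-missing. Rows sharing
#' a gene symbol (e.g. multiple probes of one gene) are collapsed to the
#' per-sample maximum, a deterministic convention common in microarray
#' preprocessing.
#'
#' @param path Path to the expression TSV.
#' @param labels Either the path of a labels TSV (see [read_labels()]), a
#'   tibble as returned by it, or a named character vector mapping sample id
#'   to `"case"`/`"control"`.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, labels) {
  if (!file.exists(path)) {
    stop_gsreg(sprintf("expression table not found: %s", path), "gsreg_io_error")
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    stop_gsreg("expression table has an empty data section", "gsreg_io_error")
  }
  genes <- tab[[1L]]
  samples <- names(tab)[-1L]
  vals <- matrix(NA_real_, nrow(tab), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad) > 0L) {
      stop_gsreg(
        sprintf("non-numeric value '%s' at row %d, column '%s'", col[bad[1L]], bad[1L], samples[j]),
        "gsreg_io_error"
      )
    }
    if (anyNA(num)) {
      stop_gsreg(sprintf("missing value in column '%s'", samples[j]), "gsreg_io_error")
    }
    vals[, j] <- num
  }
  # probe collapse: per-gene maximum per sample
  if (anyDuplicated(genes)) {
    vals <- rowsum_max(vals, genes)
  } else {
    rownames(vals) <- genes
  }

  if (is.character(labels) && length(labels) == 1L && is.null(names(labels))) {
    labels <- read_labels(labels)
  }
  if (is.data.frame(labels)) {
    lab <- setNames(labels$group, labels$sample_id)
    sub <- setNames(labels$subtype, labels$sample_id)
    plat <- setNames(labels$platform, labels$sample_id)
  } else {
    lab <- labels
    sub <- NULL
    plat <- NULL
  }
  missing <- setdiff(samples, names(lab))
  if (length(missing) > 0L) {
    stop_gsreg(
      sprintf("samples in table missing from labels: %s", paste(missing, collapse = ", ")),
      "gsreg_io_error"
    )
  }
  expression_matrix(vals, lab[samples],
                    subtype = if (is.null(sub)) NULL else sub[samples],
                    platform = if (is.null(plat)) NULL else plat[samples])
}

rowsum_max <- function(vals, genes) {
  ug <- unique(genes)
  out <- matrix(NA_real_, length(ug), ncol(vals), dimnames = list(ug, colnames(vals)))
  idx <- split(seq_along(genes), factor(genes, levels = ug))
  for (g in seq_along(ug)) {
    rows <- idx[[g]]
    out[g, ] <- if (length(rows) == 1L) vals[rows, ] else apply(vals[rows, , drop = FALSE], 2L, max)
  }
  out
}

#' Write an expression matrix and its labels to TSV
#'
#' @param x An `expr_matrix`.
#' @param path Output path for the expression table.
#' @param labels_path Optional output path for the labels table.
#' @return `x`, invisibly.
#' @export
write_expression_table <- function(x, path, labels_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- as.data.frame(x$values)
  tab <- cbind(gene = rownames(x$values), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(labels_path)) {
    readr::write_tsv(
      tibble(sample_id = colnames(x$values), group = unname(x$group),
             subtype = unname(x$subtype), platform = unname(x$platform)),
      labels_path, progress = FALSE
    )
  }
  invisible(x)
}

#' Merge expression matrices across platforms
#'
#' Column-concatenates cohorts measured on different platforms, restricted to
#' the genes shared by all inputs. No value normalization is applied: the
#' gene set regularity index is computed from within-sample orderings, so
#' arbitrary monotone per-platform scales are already harmless, and only
#' gene-identifier alignment matters. Gene matching is case-sensitive and
#' exact.
#'
#' @param matrices A list of `expr_matrix` objects (a single object is
#'   also accepted).
#' @return One merged `expr_matrix` over the gene intersection.
#' @export
harmonize <- function(matrices) {
  if (inherits(matrices, "expr_matrix")) matrices <- list(matrices)
  if (length(matrices) == 0L) {
    stop_gsreg("harmonize needs at least one expression matrix", "gsreg_input_error")
  }
  stopifnot(all(vapply(matrices, inherits, logical(1), "expr_matrix")))
  genes <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (length(genes) == 0L) {
    stop_gsreg("no genes shared by all input matrices", "gsreg_harmonize_error")
  }
  all_samples <- unlist(lapply(matrices, function(m) colnames(m$values)))
  if (anyDuplicated(all_samples)) {
    stop_gsreg("duplicate sample ids across input matrices", "gsreg_harmonize_error")
  }
  values <- do.call(cbind, lapply(matrices, function(m) m$values[genes, , drop = FALSE]))
  expression_matrix(
    values,
    group = unlist(lapply(matrices, function(m) m$group)),
    subtype = unlist(lapply(matrices, function(m) m$subtype)),
    platform = unlist(lapply(matrices, function(m) m$platform))
  )
}
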