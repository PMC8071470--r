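#' Rank genes by repetition across a category's gene sets
#'
#' For a category of ontology terms (e.g. the immune- and
#' inflammation-related terms of a common-term table), collects the genes
#' annotated to the category's gene sets, intersects them with the
#' genome-wide differentially expressed genes, and counts for each
#' significant gene how many of the category's sets contain it. Genes with
#' the highest repetition are the category's representative gene
#' candidates. Sorting is by repetition count descending, then smallest DEG
#' q-value, then gene id.
#'
#' @param category_terms Character vector of term ids; each must be a
#'   `set_id` of `collection`.
#' @param collection A [gene_set_collection()] providing the terms' gene
#'   annotations.
#' @param degs A [call_degs()] result.
#' @return A tibble of class `gene_repetition`: `rank`, `gene_id`,
#'   `n_sets`, `best_q`. Empty when no DEG is significant.
#' @export
rank_repetition <- function(category_terms, collection, degs) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(category_terms) == 0L) {
    stop_gsreg("category_terms must be non-empty", "gsreg_input_error")
  }
  missing <- setdiff(category_terms, collection$set_id)
  if (length(missing) > 0L) {
    stop_gsreg(
      sprintf("category term absent from collection: %s", paste(missing, collapse = ", ")),
      "gsreg_input_error"
    )
  }
  sig <- degs[degs$significant, , drop = FALSE]
  sets <- collection$genes[match(unique(category_terms), collection$set_id)]
  hits <- unlist(lapply(sets, function(g) intersect(g, sig$gene_id)))
  counts <- table(hits)
  out <- tibble(
    gene_id = if (length(counts)) names(counts) else character(0),
    n_sets = as.integer(counts),
    best_q = sig$q[match(if (length(counts)) names(counts) else character(0), sig$gene_id)]
  )
  out <- arrange(out, desc(.data$n_sets), .data$best_q, .data$gene_id)
  out <- mutate(out, rank = row_number())
  out <- out[, c("rank", "gene_id", "n_sets", "best_q")]
  class(out) <- c("gene_repetition", class(out))
  out
}

#' First k entries of a repetition ranking
#'
#' @param reps A [rank_repetition()] result (any ordered tibble works).
#' @param k Number of entries to keep (>= 0); fewer are returned when the
#'   list is shorter.
#' @return The first `k` rows.
#' @export
top_k <- function(reps, k) {
  if (!is_scalar_number(k) || k < 0) {
    stop_gsreg("k must be a non-negative number", "gsreg_input_error")
  }
  head(reps, k)
}
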