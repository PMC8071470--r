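#' Construct a gene set collection
#'
#' A collection is a tibble with one row per gene set: `set_id` (unique
#' identifier such as a GO accession or pathway name), `name` (display
#' string) and `genes` (a list-column of unique gene symbols). Collections
#' are the unit the functionome is built over; a `source_tag` attribute
#' distinguishes ontology-derived sets from canonical pathways.
#'
#' @param set_id Character vector of unique set identifiers.
#' @param name Character vector of display names (recycled from `set_id`
#'   when omitted).
#' @param genes List of character vectors of gene symbols; duplicates within
#'   a set are dropped keeping first occurrence.
#' @param source_tag `"GO"` or `"canonical_pathway"` (free text allowed).
#' @return A tibble of class `gene_set_collection`.
#' @export
gene_set_collection <- function(set_id, genes, name = set_id, source_tag = "GO") {
  set_id <- as.character(set_id)
  if (anyDuplicated(set_id)) {
    stop_gsreg("set ids must be unique within a collection", "gsreg_input_error")
  }
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (any(lengths(genes) < 1L)) {
    stop_gsreg("every gene set needs at least one gene", "gsreg_input_error")
  }
  out <- tibble(set_id = set_id, name = as.character(name), genes = genes)
  class(out) <- c("gene_set_collection", class(out))
  attr(out, "source_tag") <- source_tag
  out
}

#' Read a GMT gene set file
#'
#' One set per line: identifier, description, then gene symbols, all
#' tab-separated. Duplicate symbols within a line are de-duplicated
#' preserving first occurrence.
#'
#' @param path Path to the GMT file.
#' @param source_tag Collection tag, e.g. `"GO"` or `"canonical_pathway"`.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, source_tag = "GO") {
  if (!file.exists(path)) {
    stop_gsreg(sprintf("GMT file not found: %s", path), "gsreg_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop_gsreg("GMT file has no gene set lines", "gsreg_io_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop_gsreg(
      sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", short[1L]),
      "gsreg_parse_error"
    )
  }
  gene_set_collection(
    set_id = vapply(fields, `[[`, character(1), 1L),
    name = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)])),
    source_tag = source_tag
  )
}

#' Write a gene set collection to GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `collection`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set_id[i], collection$name[i], collection$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (%s), set sizes %d-%d\n",
              nrow(x), attr(x, "source_tag") %||% "untagged",
              min(lengths(x$genes)), max(lengths(x$genes))))
  NextMethod()
}
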