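#' Construct an ontology graph
#'
#' A directed acyclic graph of `is_a` relations, edges pointing child to
#' parent. Only `is_a` edges participate in term clustering; `part_of` and
#' other relation types are ignored throughout the package.
#'
#' @param terms Tibble or data frame with columns `id` and `name`, one row
#'   per term.
#' @param edges Tibble or data frame with columns `child` and `parent`
#'   (term ids). May have zero rows.
#' @return An object of class `ontology_graph` wrapping an igraph.
#' @export
ontology_graph <- function(terms, edges) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  stopifnot(all(c("id", "name") %in% names(terms)),
            all(c("child", "parent") %in% names(edges)))
  if (anyDuplicated(terms$id)) {
    stop_gsreg("duplicate term ids in ontology", "gsreg_input_error")
  }
  loose <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(loose) > 0L) {
    stop_gsreg(
      sprintf("edge endpoints missing from term list: %s", paste(head(loose, 5), collapse = ", ")),
      "gsreg_input_error"
    )
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$child, to = edges$parent),
    directed = TRUE,
    vertices = data.frame(name = terms$id, term_name = terms$name)
  )
  if (!igraph::is_dag(g)) {
    stop_gsreg("ontology graph contains a cycle in its is_a relations", "gsreg_cycle_error")
  }
  structure(list(graph = g, terms = terms), class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d terms, %d is_a edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Read an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas, keeping `id`, `name` and `is_a` fields. Terms
#' marked `is_obsolete: true` are dropped, together with any edge touching
#' them. Cyclic `is_a` relations are an error.
#'
#' @param path Path to the OBO file.
#' @return An [ontology_graph()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) {
    stop_gsreg(sprintf("OBO file not found: %s", path), "gsreg_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  starts <- which(trimws(lines) == "[Term]")
  if (length(starts) == 0L) {
    stop_gsreg("no [Term] stanzas found in OBO file", "gsreg_parse_error")
  }
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0)
  children <- character(0); parents <- character(0)
  for (k in seq_along(starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\[", chunk)]
    field <- function(tag) {
      hit <- grep(paste0("^", tag, ":"), chunk, value = TRUE)
      trimws(sub("!.*$", "", sub(paste0("^", tag, ":"), "", hit)))
    }
    id <- field("id")[1]
    if (is.na(id) || !nzchar(id)) next
    if (any(tolower(field("is_obsolete")) == "true")) next
    ids <- c(ids, id)
    nm <- field("name")[1]
    nms <- c(nms, if (is.na(nm)) id else nm)
    isa <- field("is_a")
    if (length(isa) > 0L) {
      children <- c(children, rep(id, length(isa)))
      parents <- c(parents, isa)
    }
  }
  keep <- parents %in% ids  # edges into obsolete/undeclared terms dropped
  ontology_graph(
    terms = tibble(id = ids, name = nms),
    edges = tibble(child = children[keep], parent = parents[keep])
  )
}

#' Write an ontology graph as a minimal OBO 1.2 file
#'
#' Emits one `[Term]` stanza per node with its `is_a` parents; intended for
#' generating self-contained fixtures alongside synthetic cohorts.
#'
#' @param ontology An [ontology_graph()].
#' @param path Output path.
#' @return `ontology`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "ontology_graph"))
  el <- igraph::as_edgelist(ontology$graph)
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(ontology$terms))) {
    id <- ontology$terms$id[i]
    pars <- el[el[, 1] == id, 2]
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", ontology$terms$name[i]),
             if (length(pars)) paste0("is_a: ", pars), "")
  }
  writeLines(out, path)
  invisible(ontology)
}

#' Ancestors of a term under is_a
#'
#' Transitive closure of the child-to-parent relation, excluding the term
#' itself.
#'
#' @param ontology An [ontology_graph()].
#' @param id Term id.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
ontology_ancestors <- function(ontology, id) {
  stopifnot(inherits(ontology, "ontology_graph"))
  if (!id %in% ontology$terms$id) {
    stop_gsreg(sprintf("term not in ontology: %s", id), "gsreg_input_error")
  }
  anc <- igraph::subcomponent(ontology$graph, id, mode = "out")
  setdiff(names(anc), id)
}
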