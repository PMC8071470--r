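#' Cluster significant ontology terms and compute cluster weight indices
#'
#' Groups the significant gene set test results into clusters of the
#' ontology graph: every significant term is assigned to exactly one cluster
#' headed by its highest significant ancestor — the significant ancestor
#' farthest from the term along `is_a` edges — and a significant term with
#' no significant ancestor heads its own cluster. Significant ids absent
#' from the ontology form singleton clusters. Each cluster's weight is the
#' sum over members of -log10 of the raw p-value (or of 1 - p with
#' `weight = "one_minus_p"`), and the cluster weight index (CWI) is the
#' cluster weight divided by the summed weight of all clusters, so CWI sums
#' to 1 and ranks clusters by relevance.
#'
#' The head-assignment rule and the -log10 weight are deterministic
#' interpretations of ontology-tree clustering chosen for this package;
#' both are documented in the methods vignette.
#'
#' @param tests A [call_dysregulated()] result (or any tibble with
#'   `set_id`, `p_raw`, `significant`).
#' @param ontology An [ontology_graph()].
#' @param weight Member weight function: `"neglog10"` (default) or
#'   `"one_minus_p"`.
#' @return A tibble of class `go_clusters`, one row per cluster:
#'   `head_term`, `head_name`, `head_p`, `members` (list-column),
#'   `n_members`, `weight`, `cwi`.
#' @export
build_clusters <- function(tests, ontology, weight = c("neglog10", "one_minus_p")) {
  weight <- match.arg(weight)
  stopifnot(inherits(ontology, "ontology_graph"))
  sig <- tests[tests$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    out <- tibble(head_term = character(), head_name = character(),
                  head_p = double(), members = list(), n_members = integer(),
                  weight = double(), cwi = double())
    class(out) <- c("go_clusters", class(out))
    return(out)
  }
  sig_ids <- sig$set_id
  p_by_id <- setNames(sig$p_raw, sig_ids)
  in_graph <- sig_ids %in% ontology$terms$id

  # distance (in edges) from each in-graph significant term to each of its
  # significant ancestors; head = farthest significant ancestor.
  head_of <- setNames(sig_ids, sig_ids)  # default: self-headed
  if (any(in_graph)) {
    g <- ontology$graph
    dist <- igraph::distances(g, v = sig_ids[in_graph],
                              to = intersect(sig_ids, ontology$terms$id),
                              mode = "out")
    for (t in sig_ids[in_graph]) {
      d <- dist[t, ]
      anc <- names(d)[is.finite(d) & d > 0]  # significant proper ancestors
      if (length(anc) == 0L) next
      # candidate heads: significant ancestors that are themselves unheaded
      cand <- anc[vapply(anc, function(a) {
        da <- dist[a, ]
        !any(is.finite(da) & da > 0)  # a has no significant proper ancestor
      }, logical(1))]
      if (length(cand) == 0L) next
      ord <- order(-d[cand], p_by_id[cand], cand, method = "radix")
      head_of[t] <- cand[ord[1L]]
    }
  }

  w_fun <- if (weight == "neglog10") {
    function(p) -log10(pmax(p, 1e-300))
  } else {
    function(p) 1 - p
  }
  clusters <- split(sig_ids, head_of[sig_ids])
  name_of <- setNames(ontology$terms$name, ontology$terms$id)
  out <- purrr::map_dfr(sort(names(clusters)), function(h) {
    mem <- sort(clusters[[h]])
    tibble(
      head_term = h,
      head_name = unname(name_of[h]),
      head_p = unname(p_by_id[h]),
      members = list(mem),
      n_members = length(mem),
      weight = sum(w_fun(p_by_id[mem]))
    )
  })
  out$head_name[is.na(out$head_name)] <- out$head_term[is.na(out$head_name)]
  out$cwi <- out$weight / sum(out$weight)
  class(out) <- c("go_clusters", class(out))
  out
}

#' Rank clusters by cluster weight index
#'
#' Descending CWI; ties broken by smaller head-term raw p-value, then by
#' lexicographic head id. Adds a `rank` column.
#'
#' @param clusters A [build_clusters()] result.
#' @return The same tibble, ordered, with a leading `rank` column.
#' @export
rank_clusters <- function(clusters) {
  stopifnot(inherits(clusters, "go_clusters"))
  if (nrow(clusters) == 0L) {
    stop_gsreg("no clusters to rank", "gsreg_input_error")
  }
  ord <- order(-clusters$cwi, clusters$head_p, clusters$head_term, method = "radix")
  out <- clusters[ord, , drop = FALSE]
  out <- mutate(out, rank = row_number())
  out[, c("rank", setdiff(names(out), "rank"))]
}

#' Common top terms across case groups
#'
#' Intersects each group's top-k cluster head terms and orders the common
#' terms by the ascending mean of their within-group ranks, reporting each
#' group's original rank alongside.
#'
#' @param ranked_per_group Named list (>= 2 groups) of [rank_clusters()]
#'   results, or of character vectors of head terms in rank order.
#' @param k Depth of each group's top list (default 50).
#' @return A tibble of class `common_term_table`: `order`, `term`,
#'   `mean_rank`, and one `rank_<group>` column per group. Empty (zero
#'   rows) when the intersection is empty.
#' @export
common_top_terms <- function(ranked_per_group, k = 50) {
  if (length(ranked_per_group) < 2L || is.null(names(ranked_per_group))) {
    stop_gsreg("ranked_per_group must be a named list of at least two groups", "gsreg_input_error")
  }
  if (!is_scalar_number(k) || k < 1) {
    stop_gsreg("k must be a positive number", "gsreg_input_error")
  }
  tops <- lapply(ranked_per_group, function(r) {
    ids <- if (is.character(r)) r else r$head_term
    head(ids, k)
  })
  common <- Reduce(intersect, tops)
  ranks <- lapply(tops, function(ids) match(common, ids))
  out <- tibble(term = common)
  for (g in names(tops)) out[[paste0("rank_", g)]] <- ranks[[g]]
  out$mean_rank <- rowMeans(as.matrix(as.data.frame(ranks)))
  out <- arrange(out, .data$mean_rank, .data$term)
  out <- mutate(out, order = row_number())
  out <- out[, c("order", "term", "mean_rank",
                 paste0("rank_", names(tops)))]
  class(out) <- c("common_term_table", class(out))
  out
}

#' Assign common terms to functional categories
#'
#' Partitions a common-term table using a term-to-category map (for
#' instance the packaged borderline-ovarian-tumour reference assignments,
#' [bot_common_go_terms()]); terms absent from the map fall into
#' `"others"`.
#'
#' @param table A [common_top_terms()] result, or any tibble with a `term`
#'   column.
#' @param category_map Named character vector (names = term ids, values =
#'   category labels) or a tibble/data frame with columns `term` and
#'   `category`.
#' @return The input table with an added `category` column, ordered by
#'   category then original order.
#' @export
categorize_terms <- function(table, category_map) {
  stopifnot("term" %in% names(table))
  if (is.data.frame(category_map)) {
    category_map <- setNames(category_map$category, category_map$term)
  }
  cat <- unname(category_map[table$term])
  cat[is.na(cat)] <- "others"
  out <- mutate(table, category = cat)
  arrange(out, .data$category, dplyr::across(dplyr::any_of("order")))
}
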