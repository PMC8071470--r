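#' Configuration for synthetic cohort generation
#'
#' Captures the study conditions the simulator emulates: a two-group cohort
#' (possibly unbalanced, as real case series are), a latent gene score per
#' gene shared by all samples, Gaussian per-sample jitter, optional
#' per-sample monotone intensity scales standing in for platform
#' heterogeneity, and a planted subset of gene sets whose within-set
#' orderings are inverted in case samples at a tunable strength.
#'
#' Defaults correspond to the simulation conditions used throughout the
#' package's own validation: 30 vs 30 samples, 1000 genes, 200 sets of 10
#' genes, a quarter of sets planted, strength 0.8, noise SD 0.3 (about a
#' third of the unit spacing scale of the latent standard-normal gene
#' scores).
#'
#' @param n_case,n_control Sample counts (positive integers).
#' @param n_genes Size of the gene universe.
#' @param n_sets Number of gene sets to simulate.
#' @param set_size Integer range `c(min, max)` of genes per set (a single
#'   number fixes the size).
#' @param planted_fraction Fraction of sets dysregulated in cases, in
#'   \[0, 1\].
#' @param scramble_strength Fraction of within-set gene pair orderings
#'   inverted in case samples, in \[0, 1\]; 1 reverses the set completely.
#' @param noise_sd Standard deviation of per-sample Gaussian jitter added to
#'   the latent gene scores.
#' @param monotone_scales Apply a random strictly increasing transform per
#'   sample (platform-like intensity scales). Invisible to rank-based
#'   downstream analysis by construction.
#' @param seed Integer master seed; all randomness flows from it through
#'   named substreams.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_case = 30, n_control = 30, n_genes = 1000,
                             n_sets = 200, set_size = 10,
                             planted_fraction = 0.25, scramble_strength = 0.8,
                             noise_sd = 0.3, monotone_scales = TRUE, seed = 1) {
  if (length(set_size) == 1L) set_size <- c(set_size, set_size)
  counts <- c(n_case = n_case, n_control = n_control, n_genes = n_genes, n_sets = n_sets)
  if (any(counts < 1L)) {
    stop_gsreg("sample, gene and set counts must be positive", "gsreg_config_error")
  }
  if (planted_fraction < 0 || planted_fraction > 1 ||
      scramble_strength < 0 || scramble_strength > 1) {
    stop_gsreg("planted_fraction and scramble_strength must lie in [0, 1]", "gsreg_config_error")
  }
  if (noise_sd < 0) stop_gsreg("noise_sd must be non-negative", "gsreg_config_error")
  if (set_size[2L] > n_genes) {
    stop_gsreg("set size exceeds the gene universe", "gsreg_config_error")
  }
  if (set_size[1L] < 2L) stop_gsreg("sets need at least 2 genes", "gsreg_config_error")
  structure(
    list(n_case = as.integer(n_case), n_control = as.integer(n_control),
         n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
         set_size = as.integer(set_size), planted_fraction = planted_fraction,
         scramble_strength = scramble_strength, noise_sd = noise_sd,
         monotone_scales = isTRUE(monotone_scales), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a seeded synthetic gene set collection
#'
#' Sets are sampled without replacement within a set (no duplicate genes)
#' but may overlap across sets, mirroring real ontology collections where a
#' gene annotates many terms.
#'
#' @param config A [synthetic_config()].
#' @return A [gene_set_collection()] with ids `SET0001`, `SET0002`, ...
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "collection"))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  size_range <- seq(config$set_size[1L], config$set_size[2L])
  sizes <- if (length(size_range) == 1L) rep.int(size_range, config$n_sets) else
    sample(size_range, config$n_sets, replace = TRUE)
  gene_set_collection(
    set_id = sprintf("SET%04d", seq_len(config$n_sets)),
    name = sprintf("synthetic gene set %d", seq_len(config$n_sets)),
    genes = lapply(sizes, function(sz) sample(genes, sz)),
    source_tag = "GO"
  )
}

# Permutation of 1..m at exact Kendall (inversion) distance d from the
# identity, built by adjacent transpositions each adding one inversion.
# d = m(m-1)/2 yields the full reversal.
permutation_with_inversions <- function(m, d) {
  max_d <- m * (m - 1L) / 2L
  stopifnot(d >= 0L, d <= max_d)
  perm <- seq_len(m)
  for (step in seq_len(d)) {
    asc <- which(perm[-m] < perm[-1L])
    i <- if (length(asc) == 1L) asc else sample(asc, 1L)
    perm[c(i, i + 1L)] <- perm[c(i + 1L, i)]
  }
  perm
}

#' Generate a synthetic two-group cohort with planted dysregulation
#'
#' Controls are latent baseline gene scores (standard normal, one draw per
#' gene) plus per-sample Gaussian jitter. Cases share the baseline except
#' that for each planted set the latent scores of its genes are permuted so
#' that an exact fraction of the set's gene pairs — `scramble_strength`,
#' rounded to the nearest achievable inversion count — is oppositely ordered
#' relative to the control baseline; strength 1 is the full reversal.
#' Because the GSR statistic is purely ordinal, dysregulation must move rank
#' orderings: mean shifts that preserve order would be invisible to it.
#' Noise is applied after planting, so the realized order inversion seen by
#' the analysis is attenuated at high noise; the exact planted inversion
#' fraction per set is recorded in the truth object. Genes shared between a
#' planted and an unplanted set leak signal into the latter, as overlapping
#' ontology sets do in real data.
#'
#' @param config A [synthetic_config()].
#' @param collection A [gene_set_collection()], typically from
#'   [generate_collection()].
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (list: `planted_set_ids`, `group` labels, and a `planting`
#'   tibble with the per-set realized inversion fraction).
#' @export
generate_cohort <- function(config, collection) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(collection, "gene_set_collection"))
  n_planted <- round(config$planted_fraction * nrow(collection))
  if (config$planted_fraction > 0 && nrow(collection) == 0L) {
    stop_gsreg("cannot plant dysregulation into an empty collection", "gsreg_config_error")
  }
  genes <- sprintf("G%05d", seq_len(config$n_genes))

  set.seed(substream_seed(config$seed, "baseline"))
  base <- setNames(rnorm(config$n_genes), genes)

  set.seed(substream_seed(config$seed, "planting"))
  planted <- sort(sample(collection$set_id, n_planted))
  case_base <- base
  planting <- list()
  for (sid in planted) {
    sg <- collection$genes[[match(sid, collection$set_id)]]
    sg <- sg[sg %in% genes]
    m <- length(sg)
    if (m < 2L) next
    n_pairs <- m * (m - 1L) / 2L
    d <- as.integer(round(config$scramble_strength * n_pairs))
    # permute the multiset of current latent values among the set's genes:
    # order genes by current value, then move the value at sorted position
    # perm[k] to the gene at sorted position k.
    ord <- order(case_base[sg], lex_rank(sg))
    perm <- permutation_with_inversions(m, d)
    case_base[sg[ord]] <- case_base[sg[ord]][perm]
    planting[[length(planting) + 1L]] <- tibble(
      set_id = sid, n_pairs = n_pairs, pairs_inverted = d,
      realized_strength = d / n_pairs
    )
  }

  n <- config$n_case + config$n_control
  set.seed(substream_seed(config$seed, "noise"))
  noise <- matrix(rnorm(config$n_genes * n, 0, config$noise_sd), config$n_genes, n)
  values <- cbind(
    matrix(case_base, config$n_genes, config$n_case) +
      noise[, seq_len(config$n_case), drop = FALSE],
    matrix(base, config$n_genes, config$n_control) +
      noise[, config$n_case + seq_len(config$n_control), drop = FALSE]
  )
  if (config$monotone_scales) {
    set.seed(substream_seed(config$seed, "scales"))
    a <- runif(n, 0.5, 2)
    b <- runif(n, 0.5, 1.5)
    for (j in seq_len(n)) values[, j] <- a[j] * exp(b[j] * values[, j])
  }
  sample_ids <- c(sprintf("case_%03d", seq_len(config$n_case)),
                  sprintf("ctrl_%03d", seq_len(config$n_control)))
  dimnames(values) <- list(genes, sample_ids)
  group <- setNames(rep(c("case", "control"), c(config$n_case, config$n_control)),
                    sample_ids)
  mat <- expression_matrix(values, group,
                           platform = rep("synthetic", n))
  truth <- list(
    planted_set_ids = planted,
    group = group,
    planting = if (length(planting)) bind_rows(planting) else
      tibble(set_id = character(), n_pairs = integer(),
             pairs_inverted = integer(), realized_strength = double())
  )
  list(matrix = mat, truth = truth)
}

#' Generate a synthetic ontology over a collection
#'
#' A random forest-shaped DAG whose leaves are the collection's set ids,
#' grouped under synthetic parent terms; with `depth` levels of parents,
#' each node is assigned exactly one parent at the next level, so the graph
#' is acyclic by construction.
#'
#' @param collection A [gene_set_collection()].
#' @param depth Number of parent levels above the leaves (>= 1).
#' @param n_parents Number of parent terms at the first level; defaults to
#'   roughly one per five leaves. Higher levels shrink by the same factor.
#' @param seed Integer seed.
#' @return An [ontology_graph()] containing the leaves and all parents.
#' @export
generate_ontology <- function(collection, depth = 2, n_parents = NULL, seed = 1) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (depth < 1L) stop_gsreg("ontology depth must be >= 1", "gsreg_config_error")
  set.seed(substream_seed(seed, "ontology"))
  level_ids <- collection$set_id
  terms <- tibble(id = collection$set_id, name = collection$name)
  children <- character(0); parents <- character(0)
  n_par <- n_parents %||% max(1L, ceiling(length(level_ids) / 5))
  for (lev in seq_len(depth)) {
    par_ids <- sprintf("SYN:L%d_%03d", lev, seq_len(n_par))
    terms <- bind_rows(terms, tibble(id = par_ids,
                                     name = sprintf("synthetic parent level %d #%d", lev, seq_len(n_par))))
    assign_to <- if (length(par_ids) == 1L) rep(1L, length(level_ids)) else
      sample(seq_along(par_ids), length(level_ids), replace = TRUE)
    children <- c(children, level_ids)
    parents <- c(parents, par_ids[assign_to])
    level_ids <- par_ids
    n_par <- max(1L, ceiling(n_par / 5))
  }
  ontology_graph(terms, tibble(child = children, parent = parents))
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits everything an end-to-end run reads: the expression TSV, the labels
#' TSV, the GMT collection, the OBO ontology fixture, and a truth JSON
#' naming the planted sets.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @param depth,n_parents Passed to [generate_ontology()].
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_inputs <- function(config, dir, depth = 2, n_parents = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  collection <- generate_collection(config)
  cohort <- generate_cohort(config, collection)
  ontology <- generate_ontology(collection, depth = depth,
                                n_parents = n_parents, seed = config$seed)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    gmt = file.path(dir, "sets.gmt"),
    obo = file.path(dir, "ontology.obo"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_table(cohort$matrix, paths$expression, paths$labels)
  write_gmt(collection, paths$gmt)
  write_obo(ontology, paths$obo)
  jsonlite::write_json(
    list(planted_set_ids = cohort$truth$planted_set_ids,
         planting = cohort$truth$planting,
         config = unclass(config)),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
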