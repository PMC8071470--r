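#' Configuration of an end-to-end pipeline run
#'
#' Either a synthetic run (supply `synthetic`, a [synthetic_config()]) or a
#' run on user data (supply `expression`, `labels` and `gmt` paths, plus
#' optionally `obo`). A canonical-pathway GMT can be given in addition for
#' the pathway-ranking stage.
#'
#' @param synthetic A [synthetic_config()], or `NULL` for a real-data run.
#' @param expression,labels,gmt,obo Input file paths for a real-data run.
#' @param pathway_gmt Optional canonical-pathway GMT path; on synthetic runs
#'   the ordinary collection doubles as the pathway collection when this is
#'   `NULL`.
#' @param alpha Significance threshold in (0, 1).
#' @param n_folds,n_repeats Cross-validation shape.
#' @param seed Master seed for classification shuffles (synthetic
#'   generation uses the seed inside `synthetic`).
#' @param out_dir Output directory for all stage TSVs and the manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, expression = NULL, labels = NULL,
                       gmt = NULL, obo = NULL, pathway_gmt = NULL,
                       alpha = 0.05, n_folds = 5, n_repeats = 10,
                       seed = 1, out_dir = tempfile("gsreg_run_")) {
  if (is.null(synthetic) && (is.null(expression) || is.null(labels) || is.null(gmt))) {
    stop_gsreg("supply either a synthetic config or expression + labels + gmt paths",
               "gsreg_config_error")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    stop_gsreg("`synthetic` must be a synthetic_config", "gsreg_config_error")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_gsreg("alpha must lie strictly between 0 and 1", "gsreg_config_error")
  }
  structure(
    list(synthetic = synthetic, expression = expression, labels = labels,
         gmt = gmt, obo = obo, pathway_gmt = pathway_gmt, alpha = alpha,
         n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full functionome analysis pipeline
#'
#' Executes the stages in order — input assembly, functionome construction,
#' dysregulation statistics, ontology clustering, SVM classification,
#' pathway ranking and representative-gene selection — writing one TSV per
#' report into `config$out_dir` and a JSON manifest recording the seed and
#' the stage-level counts (sets in the collection, sets retained, sets
#' significant, clusters), so the silent filters stay auditable. Any stage
#' error aborts the run with the stage name, and partially written outputs
#' are removed. Runs are byte-identical under a fixed configuration.
#'
#' On synthetic runs the representative-gene stage uses the top-ranked
#' cluster heads as a stand-in category, since synthetic sets carry no
#' functional category labels.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(tab, name) {
    path <- file.path(config$out_dir, name)
    readr::write_tsv(tab, path, progress = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop_gsreg(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
                 "gsreg_stage_error")
    })
  }

  inputs <- stage("data_io", {
    if (!is.null(config$synthetic)) {
      collection <- generate_collection(config$synthetic)
      cohort <- generate_cohort(config$synthetic, collection)
      ontology <- generate_ontology(collection, seed = config$synthetic$seed)
      list(matrix = cohort$matrix, collection = collection, ontology = ontology,
           truth = cohort$truth)
    } else {
      collection <- read_gmt(config$gmt)
      mat <- read_expression_table(config$expression, config$labels)
      ontology <- if (!is.null(config$obo)) read_obo(config$obo) else NULL
      list(matrix = mat, collection = collection, ontology = ontology, truth = NULL)
    }
  })

  f <- stage("gsr_core", build_functionome(inputs$matrix, inputs$collection))
  stage("gsr_core", {
    write_functionome(f, file.path(config$out_dir, "functionome.tsv"),
                      file.path(config$out_dir, "skipped_sets.tsv"))
    written <- c(written, file.path(config$out_dir, c("functionome.tsv", "skipped_sets.tsv")))
  })

  stats_out <- stage("dysregulation_stats", {
    tests <- call_dysregulated(f, alpha = config$alpha)
    emit(tests, "set_tests.tsv")
    hist <- summarize_histogram(f)
    emit(hist$bins, "gsr_histogram.tsv")
    emit(hist$summary, "group_summary.tsv")
    tests
  })

  clusters_out <- stage("go_clustering", {
    if (is.null(inputs$ontology) || !any(stats_out$significant)) {
      NULL
    } else {
      ranked <- rank_clusters(build_clusters(stats_out, inputs$ontology))
      flat <- mutate(ranked, members = vapply(.data$members, paste, character(1), collapse = ";"))
      emit(flat, "clusters.tsv")
      ranked
    }
  })

  cv <- stage("classification", {
    rep <- cv_classify(f, n_folds = config$n_folds, n_repeats = config$n_repeats,
                       seed = config$seed)
    emit(glance(rep), "classification_report.tsv")
    rep
  })

  pathways <- stage("pathway_rank", {
    ptests <- if (!is.null(config$pathway_gmt)) {
      pf <- build_functionome(inputs$matrix, read_gmt(config$pathway_gmt,
                                                      source_tag = "canonical_pathway"))
      call_dysregulated(pf, alpha = config$alpha)
    } else {
      stats_out
    }
    ranked <- pathway_rank(ptests)
    emit(ranked, "pathway_rank.tsv")
    ranked
  })

  genes_out <- stage("gene_linkage", {
    degs <- call_degs(inputs$matrix, alpha = config$alpha)
    emit(degs, "gene_tests.tsv")
    category <- if (!is.null(clusters_out) && nrow(clusters_out) > 0L) {
      head(clusters_out$head_term, 5L)
    } else if (any(stats_out$significant)) {
      head(stats_out$set_id[stats_out$significant], 5L)
    } else {
      NULL
    }
    if (is.null(category)) {
      NULL
    } else {
      reps <- rank_repetition(category, inputs$collection, degs)
      emit(reps, "representative_genes.tsv")
      reps
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("gsreg")),
    seed = config$seed,
    alpha = config$alpha,
    synthetic = !is.null(config$synthetic),
    counts = list(
      samples = ncol(inputs$matrix$values),
      genes = nrow(inputs$matrix$values),
      sets_in_collection = nrow(inputs$collection),
      sets_retained = ncol(f$gsr),
      sets_skipped = nrow(f$skipped),
      sets_significant = sum(stats_out$significant),
      clusters = if (is.null(clusters_out)) 0L else nrow(clusters_out),
      representative_genes = if (is.null(genes_out)) 0L else nrow(genes_out)
    ),
    classification = as.list(cv$summary),
    outputs = sort(basename(c(written, file.path(config$out_dir, "manifest.json"))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Rank canonical pathways by p-value
#'
#' Orders set-level test results by ascending raw p-value (ties broken by
#' set id) — the presentation used for canonical-pathway collections, where
#' the most dysfunctional pathways head the table.
#'
#' @param results A [call_dysregulated()] result (typically from a
#'   canonical-pathway collection).
#' @param top_n Optional number of rows to keep.
#' @return The ordered tibble with a leading `rank` column.
#' @export
pathway_rank <- function(results, top_n = NULL) {
  if (nrow(results) == 0L) {
    stop_gsreg("no test results to rank", "gsreg_input_error")
  }
  ord <- order(results$p_raw, results$set_id, method = "radix")
  out <- results[ord, , drop = FALSE]
  out <- mutate(out, rank = row_number())
  out <- out[, c("rank", setdiff(names(out), "rank"))]
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}
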