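#' Curated borderline ovarian tumour reference tables
#'
#' Two small curated tables ship with the package for use as category maps
#' and smoke-test fixtures in borderline ovarian tumour (BOT) analyses:
#'
#' * `bot_common_go_terms()` — the 41 Gene Ontology terms recurrently
#'   deregulated across the all-BOT, serous-BOT and mucinous-BOT
#'   comparisons, with the per-group cluster ranks (`rank_all_bot`,
#'   `rank_sbot`, `rank_mbot`) and a functional `category` assignment:
#'   3 immune/inflammatory terms, 9 cell membrane/transporter terms, 16
#'   cell cycle/signaling terms, 9 cell metabolism terms and 4 others.
#' * `bot_category_genes()` — the 19 representative differentially
#'   expressed genes nominated for those categories by repetition counting
#'   (2, 4, 3 and 10 genes respectively).
#'
#' These tables describe an external cohort and are reference metadata, not
#' inputs the pipeline requires.
#'
#' @return A tibble (see above for columns).
#' @export
bot_common_go_terms <- function() {
  readr::read_tsv(
    system.file("extdata", "bot_common_go_terms.tsv", package = "gsreg"),
    col_types = readr::cols(
      order = readr::col_integer(),
      term = readr::col_character(),
      name = readr::col_character(),
      rank_all_bot = readr::col_integer(),
      rank_sbot = readr::col_integer(),
      rank_mbot = readr::col_integer(),
      category = readr::col_character()
    ),
    progress = FALSE
  )
}

#' @rdname bot_common_go_terms
#' @export
bot_category_genes <- function() {
  readr::read_tsv(
    system.file("extdata", "bot_category_genes.tsv", package = "gsreg"),
    col_types = readr::cols(gene = readr::col_character(),
                            category = readr::col_character()),
    progress = FALSE
  )
}
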