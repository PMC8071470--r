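#' Mann-Whitney U test between case and control values
#'
#' Two-sided rank-sum comparison of one gene set's GSR indices (or one
#' gene's expression values) between groups. The exact null distribution is
#' used when both groups have at most 8 observations and there are no ties;
#' otherwise the normal approximation with continuity and tie correction is
#' applied. `u_statistic` counts case-control pairs in which the case value
#' is larger.
#'
#' @param case,control Numeric vectors, both non-empty.
#' @param set_id Identifier carried into the result row.
#' @return A one-row tibble: `set_id`, `u_statistic`, `p_raw`, `direction`
#'   (sign of case median minus control median).
#' @export
mann_whitney_set <- function(case, control, set_id = NA_character_) {
  if (length(case) < 1L || length(control) < 1L) {
    stop_gsreg("both groups need at least one observation", "gsreg_input_error")
  }
  ties <- anyDuplicated(c(case, control)) > 0L
  exact <- length(case) <= 8L && length(control) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(case, control, alternative = "two.sided",
                exact = exact, correct = TRUE)
  )
  p <- wt$p.value
  # fully tied data degenerates the normal approximation (0/0); there is no
  # evidence against the null in that case
  if (is.na(p)) p <- 1
  tibble(
    set_id = set_id,
    u_statistic = unname(wt$statistic),
    p_raw = min(p, 1),
    direction = sign(median(case) - median(control))
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement; ties
#' are preserved and the input order is restored.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_gsreg("p-values must lie in [0, 1]", "gsreg_input_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Call dysregulated gene sets from a functionome
#'
#' Tests every retained gene set's GSR indices between cases and controls
#' with the Mann-Whitney U test and controls the false discovery rate with
#' the Benjamini-Hochberg procedure. By default significance is declared on
#' the adjusted values at `alpha`; `adjust = FALSE` thresholds raw p-values
#' instead.
#'
#' @param f A [build_functionome()] result with both groups present.
#' @param alpha Significance threshold (default 0.05).
#' @param adjust Threshold BH-adjusted q-values (default) or raw p-values.
#' @return A tibble of class `gsr_set_tests`, one row per set: `set_id`,
#'   `u_statistic`, `p_raw`, `q`, `significant`, `direction`.
#' @export
call_dysregulated <- function(f, alpha = 0.05, adjust = TRUE) {
  stopifnot(inherits(f, "functionome"))
  test_value_matrix(t(f$gsr), f$group, alpha, adjust, id_col = "set_id",
                    result_class = "gsr_set_tests")
}

#' Call differentially expressed genes
#'
#' Gene-level analogue of [call_dysregulated()]: each gene's expression
#' values are compared between cases and controls genome-wide with the same
#' test and false-discovery policy.
#'
#' @param x An `expr_matrix` with both groups present.
#' @inheritParams call_dysregulated
#' @return A tibble of class `gsr_gene_tests`, one row per gene: `gene_id`,
#'   `u_statistic`, `p_raw`, `q`, `significant`, `direction`.
#' @export
call_degs <- function(x, alpha = 0.05, adjust = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  test_value_matrix(x$values, x$group, alpha, adjust, id_col = "gene_id",
                    result_class = "gsr_gene_tests")
}

# rows of `values` are features; `group` labels the columns.
test_value_matrix <- function(values, group, alpha, adjust, id_col, result_class) {
  if (!all(c("case", "control") %in% group)) {
    stop_gsreg("both case and control groups are required", "gsreg_input_error")
  }
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1) {
    stop_gsreg("alpha must be a single number in [0, 1]", "gsreg_input_error")
  }
  case_cols <- group == "case"
  res <- purrr::map_dfr(seq_len(nrow(values)), function(i) {
    mann_whitney_set(values[i, case_cols], values[i, !case_cols],
                     set_id = rownames(values)[i])
  })
  res$q <- bh_adjust(res$p_raw)
  res$significant <- if (adjust) res$q < alpha else res$p_raw < alpha
  res <- res[, c("set_id", "u_statistic", "p_raw", "q", "significant", "direction")]
  names(res)[1L] <- id_col
  class(res) <- c(result_class, class(res))
  attr(res, "alpha") <- alpha
  attr(res, "adjusted") <- adjust
  res
}

#' Histogram summary of a functionome
#'
#' Per-group counts of GSR indices over equal-width bins of \[0, 1\],
#' together with the group means and standard deviations (identical to
#' [corrected_group_mean()] output).
#'
#' @param f A [build_functionome()] result.
#' @param n_bins Number of bins (>= 1; default 50).
#' @return A list of class `gsr_histogram` with `bins` (tibble `bin_lo`,
#'   `bin_hi`, `case_count`, `control_count`) and `summary` (tibble from
#'   [corrected_group_mean()]).
#' @export
summarize_histogram <- function(f, n_bins = 50) {
  stopifnot(inherits(f, "functionome"))
  if (!is_scalar_number(n_bins) || n_bins < 1) {
    stop_gsreg("n_bins must be a positive number", "gsreg_input_error")
  }
  n_bins <- as.integer(n_bins)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  count_group <- function(g) {
    rows <- f$group == g
    if (!any(rows)) stop_gsreg(sprintf("no samples in group '%s'", g), "gsreg_input_error")
    vals <- as.vector(f$gsr[rows, , drop = FALSE])
    # values fall in [0,1]; include the left edge in the first bin
    idx <- pmin(pmax(findInterval(vals, edges, rightmost.closed = TRUE), 1L), n_bins)
    tabulate(idx, nbins = n_bins)
  }
  structure(
    list(
      bins = tibble(bin_lo = edges[-(n_bins + 1L)], bin_hi = edges[-1L],
                    case_count = count_group("case"),
                    control_count = count_group("control")),
      summary = corrected_group_mean(f)
    ),
    class = "gsr_histogram"
  )
}

#' @export
print.gsr_histogram <- function(x, ...) {
  cat(sprintf("<gsr_histogram> %d bins over [0, 1]\n", nrow(x$bins)))
  print(x$summary)
  invisible(x)
}

#' @describeIn summarize_histogram Bar-chart rendering of the binned
#'   case/control GSR distributions.
#' @param object A `gsr_histogram`.
#' @param ... Ignored.
#' @export
autoplot.gsr_histogram <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$bins, c("case_count", "control_count"),
                             names_to = "group", values_to = "count")
  dat$group <- sub("_count$", "", dat$group)
  ggplot2::ggplot(dat, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                    y = .data$count, fill = .data$group)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55,
                      width = dat$bin_hi[1] - dat$bin_lo[1]) +
    ggplot2::scale_fill_manual(values = c(case = "#E69F00", control = "#56B4E9")) +
    ggplot2::labs(x = "GSR index", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Immunohistochemistry quantification score
#'
#' Q = I x P: staining intensity (integer grade 0-3) times percentage of
#' positive cells (0-100), giving a score with maximum 300.
#'
#' @param intensity Integer grade(s) in `{0, 1, 2, 3}`.
#' @param percent_positive Percentage(s) of positive cells in \[0, 100\].
#' @return Numeric score(s) in \[0, 300\].
#' @export
ihc_score <- function(intensity, percent_positive) {
  if (anyNA(intensity) || !all(intensity %in% 0:3)) {
    stop_gsreg("intensity must be an integer grade 0, 1, 2 or 3", "gsreg_input_error")
  }
  if (anyNA(percent_positive) || any(percent_positive < 0 | percent_positive > 100)) {
    stop_gsreg("percent_positive must lie in [0, 100]", "gsreg_input_error")
  }
  intensity * percent_positive
}
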