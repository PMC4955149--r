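#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy selection-scan results
#'
#' `tidy()` returns the per-SNP score table with a canonical `score`
#' column (the genome-normalized statistic); `glance()` returns a one-row
#' summary of the scan.
#'
#' @param x An `ihs_scan` or `xpclr_scan` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ihs_scan
#' @export
tidy.ihs_scan <- function(x, ...) {
  mutate(x$scores, score = .data$std_ihs)
}

#' @rdname tidy.ihs_scan
#' @method tidy xpclr_scan
#' @export
tidy.xpclr_scan <- function(x, ...) {
  mutate(x$scores, score = .data$std_score)
}

#' @rdname tidy.ihs_scan
#' @method glance ihs_scan
#' @export
glance.ihs_scan <- function(x, ...) {
  tibble(
    method = x$method, n_snps = nrow(x$scores),
    n_defined = sum(x$scores$defined),
    prop_defined = mean(x$scores$defined),
    maf_min = x$params$maf_min, n_bins = x$params$n_bins,
    bin_merges = x$params$bin_merges
  )
}

#' @rdname tidy.ihs_scan
#' @method glance xpclr_scan
#' @export
glance.xpclr_scan <- function(x, ...) {
  tibble(
    method = x$method, n_snps = nrow(x$scores),
    n_grid = nrow(x$grid), omega = x$params$omega,
    spacing = x$params$spacing, window_snps = x$params$window_snps,
    max_score = max(x$scores$raw_score, na.rm = TRUE)
  )
}

#' Tidy enrichment results
#'
#' @param x A `gsea_result`.
#' @param q_threshold Significance threshold on the q-value used for the
#'   `significant` flag (default 0.09).
#' @param ... Unused.
#' @return `tidy()`: the per-set result table with a `significant`
#'   column; `glance()`: one-row summary.
#' @method tidy gsea_result
#' @export
tidy.gsea_result <- function(x, q_threshold = 0.09, ...) {
  as_tibble(x) |>
    mutate(significant = !is.na(.data$q) & .data$q <= q_threshold) |>
    arrange(.data$p)
}

#' @rdname tidy.gsea_result
#' @method glance gsea_result
#' @export
glance.gsea_result <- function(x, q_threshold = 0.09, ...) {
  tibble(
    engine = attr(x, "engine"), n_sets = nrow(x),
    n_significant = sum(!is.na(x$q) & x$q <= q_threshold),
    B = attr(x, "B"), seed = attr(x, "seed")
  )
}

#' @rdname tidy.gsea_result
#' @method tidy disease_report
#' @export
tidy.disease_report <- function(x, ...) x$report

#' @rdname tidy.gsea_result
#' @method glance disease_report
#' @export
glance.disease_report <- function(x, ...) x$overlap
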