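#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline geom_vline labs theme_minimal scale_colour_manual
#' @export
ggplot2::autoplot

#' Plot a selection-score track
#'
#' Manhattan-style track of the normalized per-SNP scores, with the
#' genome-wide 99th percentile of |score| drawn as a reference line and
#' an optional vertical marker at a known sweep position.
#'
#' @param object An `ihs_scan` or `xpclr_scan`.
#' @param sweep_pos Optional true sweep position (bp) to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sweep_scan
#' @export
autoplot.sweep_scan <- function(object, sweep_pos = NULL, ...) {
  d <- tidy(object) |> filter(!is.na(.data$score))
  cutoff <- quantile(abs(d$score), 0.99)
  p <- ggplot(d, aes(x = .data$pos, y = abs(.data$score))) +
    geom_point(size = 0.4, alpha = 0.6) +
    geom_hline(yintercept = cutoff, linetype = "dashed", colour = "grey40") +
    labs(x = "position (bp)", y = "|normalized score|",
         title = sprintf("%s scan", object$method)) +
    theme_minimal()
  if (!is.null(sweep_pos)) {
    p <- p + geom_vline(xintercept = sweep_pos, colour = "red",
                        linetype = "dotted")
  }
  p
}

#' @export
autoplot.ihs_scan <- autoplot.sweep_scan

#' @export
autoplot.xpclr_scan <- autoplot.sweep_scan

#' Plot enrichment results
#'
#' Per-set -log10 q-values with the significance threshold.
#'
#' @param object A `gsea_result`.
#' @param q_threshold Significance threshold (default 0.09).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, q_threshold = 0.09, ...) {
  d <- tidy(object, q_threshold = q_threshold) |> filter(!is.na(.data$q))
  ggplot(d, aes(x = stats::reorder(.data$set, -.data$q),
                y = -log10(.data$q), fill = .data$significant)) +
    geom_col() +
    geom_hline(yintercept = -log10(q_threshold), linetype = "dashed") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "-log10(q)",
         title = sprintf("%s enrichment", attr(object, "engine"))) +
    theme_minimal()
}

#' Plot an EHH decay curve
#'
#' @param object An `ehh_curve` from [compute_ehh()].
#' @param threshold Stopping threshold to draw (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ehh_curve
#' @export
autoplot.ehh_curve <- function(object, threshold = 0.05, ...) {
  ggplot(as_tibble(object), aes(x = .data$distance_cm, y = .data$ehh)) +
    geom_line() + geom_point(size = 0.8) +
    geom_hline(yintercept = threshold, linetype = "dashed", colour = "grey40") +
    labs(x = "genetic distance from focal SNP (cM)", y = "EHH",
         subtitle = sprintf("%s of %s (allele %d), termination: %s",
                            attr(object, "direction"), attr(object, "focal"),
                            attr(object, "core_allele"),
                            attr(object, "termination"))) +
    theme_minimal()
}
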