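#' Flag outlier genes and test a disease-gene list for over-representation
#'
#' Flags genes whose selection score reaches the top `percentile` percent
#' of all gene scores (default 1%; genes tied with the cutoff value are
#' all flagged, so the flag set is invariant under monotone
#' transformations of the scores) and reports which disease-list genes are
#' among them, with a one-sided hypergeometric over-representation
#' p-value (universe = all scored genes).
#'
#' @param gene_score_tbl Gene score table (`gene_id`, `score`), e.g. from
#'   [gene_scores()].
#' @param disease_genes Character vector of disease-associated gene ids;
#'   ids absent from the score table are reported and excluded.
#' @param percentile Outlier cutoff percentile in (0, 50); default 1.
#' @return A `disease_report`: list with `report` (tibble `gene_id`,
#'   `score`, `flagged`, `in_disease_list`), `overlap` (one-row tibble:
#'   counts and the hypergeometric p), `missing` (excluded ids) and
#'   `cutoff`.
#' @export
flag_disease_genes <- function(gene_score_tbl, disease_genes, percentile = 1) {
  if (!length(disease_genes)) abort("empty disease gene list")
  if (percentile <= 0 || percentile >= 50) abort("percentile must be in (0, 50)")
  g <- as_tibble(gene_score_tbl)
  missing <- setdiff(disease_genes, g$gene_id)
  if (length(missing)) {
    inform(sprintf("%d disease gene(s) missing from the score table, excluded",
                   length(missing)))
  }
  disease <- intersect(disease_genes, g$gene_id)
  if (!length(disease)) abort("no disease gene is present in the score table")

  k <- max(1L, ceiling(percentile / 100 * nrow(g)))
  cutoff <- sort(g$score, decreasing = TRUE)[k]
  report <- g |>
    mutate(flagged = .data$score >= cutoff,
           in_disease_list = .data$gene_id %in% disease) |>
    arrange(desc(.data$score))

  n_univ <- nrow(g)
  n_flag <- sum(report$flagged)
  n_dis <- length(disease)
  n_hit <- sum(report$flagged & report$in_disease_list)
  p_over <- phyper(n_hit - 1, n_dis, n_univ - n_dis, n_flag,
                   lower.tail = FALSE)
  structure(
    list(report = report,
         overlap = tibble(n_genes = n_univ, n_flagged = n_flag,
                          n_disease = n_dis, n_overlap = n_hit,
                          p_hyper = p_over),
         missing = missing, cutoff = cutoff, percentile = percentile),
    class = "disease_report"
  )
}

#' @export
print.disease_report <- function(x, ...) {
  cat(sprintf(
    "<disease_report> %d/%d genes flagged at top %g%%; %d of %d disease genes among them (hypergeometric p = %.3g)\n",
    x$overlap$n_flagged, x$overlap$n_genes, x$percentile,
    x$overlap$n_overlap, x$overlap$n_disease, x$overlap$p_hyper
  ))
  invisible(x)
}
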