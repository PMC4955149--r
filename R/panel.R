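#' Construct a phased, polarized haplotype panel
#'
#' The panel is the central container for phased biallelic haplotype data:
#' a 0/1 matrix (rows = haplotypes, columns = SNPs) where 0 is the ancestral
#' allele, together with per-SNP physical and genetic coordinates and a
#' haplotype-to-sample-to-population assignment.
#'
#' @param haplotypes Integer matrix of 0/1 alleles, one row per haplotype,
#'   one column per SNP; 0 codes the ancestral allele.
#' @param snps Data frame with one row per SNP: `snp_id`, `chrom`,
#'   `pos` (bp, 1-based), `cm` (genetic position, centimorgans).
#' @param samples Data frame with one row per haplotype (in matrix row
#'   order): `hap_id`, `sample_id`, `population`.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, snps, samples) {
  snps <- as_tibble(snps)
  samples <- as_tibble(samples)
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != nrow(samples)) {
    abort("number of haplotype rows must equal number of sample rows")
  }
  if (ncol(haplotypes) != nrow(snps)) {
    abort("number of haplotype columns must equal number of SNP rows")
  }
  if (!all(haplotypes %in% c(0L, 1L))) {
    abort("haplotype matrix entries must be 0 (ancestral) or 1 (derived)")
  }
  need <- c("snp_id", "chrom", "pos", "cm")
  if (!all(need %in% names(snps))) {
    abort(paste("snps must contain columns:", paste(need, collapse = ", ")))
  }
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0)) {
      abort(sprintf("positions must be strictly increasing on chromosome %s", ch))
    }
  }
  if (!all(c("hap_id", "sample_id", "population") %in% names(samples))) {
    abort("samples must contain hap_id, sample_id, population")
  }
  structure(
    list(haplotypes = haplotypes, snps = snps, samples = samples),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  pops <- table(x$samples$population)
  cat(sprintf(
    "<haplotype_panel> %d haplotypes x %d SNPs (%s)\n",
    nrow(x$haplotypes), ncol(x$haplotypes),
    paste(sprintf("%s: %d", names(pops), pops), collapse = ", ")
  ))
  invisible(x)
}

#' Subset a panel to one population
#'
#' @param panel A [haplotype_panel()].
#' @param population Population label to keep.
#' @return A `haplotype_panel` restricted to the haplotypes of that population.
#' @export
panel_population <- function(panel, population) {
  keep <- panel$samples$population == population
  if (!any(keep)) abort(sprintf("no haplotypes in population '%s'", population))
  haplotype_panel(panel$haplotypes[keep, , drop = FALSE], panel$snps,
                  panel$samples[keep, , drop = FALSE])
}

#' Objective/reference frequency table for the cross-population scan
#'
#' @param panel A [haplotype_panel()] holding both populations.
#' @param objective,reference Population labels.
#' @return A tibble with `snp_id`, `freq1` (objective) and `freq2`
#'   (reference) derived-allele sample frequencies, in panel SNP order.
#' @export
population_freq_table <- function(panel, objective, reference) {
  fr <- panel_frequencies(panel)
  tibble(
    snp_id = panel$snps$snp_id,
    freq1 = fr$freq[fr$population == objective],
    freq2 = fr$freq[fr$population == reference]
  )
}

#' Per-SNP derived-allele sample frequencies
#'
#' @param panel A [haplotype_panel()].
#' @param by_population Split frequencies by population label?
#' @return A tibble with `snp_id`, (`population`,) `n_chrom`, `count`, `freq`
#'   where `freq` is the derived-allele sample frequency.
#' @export
panel_frequencies <- function(panel, by_population = TRUE) {
  groups <- if (by_population) {
    split(seq_len(nrow(panel$haplotypes)), panel$samples$population)
  } else {
    list(all = seq_len(nrow(panel$haplotypes)))
  }
  purrr::imap(groups, function(rows, pop) {
    counts <- colSums(panel$haplotypes[rows, , drop = FALSE])
    tibble(
      snp_id = panel$snps$snp_id, population = pop,
      n_chrom = length(rows), count = as.integer(counts),
      freq = counts / length(rows)
    )
  }) |>
    purrr::list_rbind()
}
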