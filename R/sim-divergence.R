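#' Simulate allele frequencies for two diverged populations
#'
#' Frequency-level counterpart of the haplotype simulator, used for the
#' cross-population scan: per-SNP ancestral frequencies are drawn from a
#' Uniform(0.05, 0.95) prior (keeping most SNPs polymorphic), each
#' population's frequency is drawn from a Balding-Nichols (beta)
#' distribution around the ancestral frequency with its differentiation
#' coefficient F, and sample allele counts are binomial at `2 n` chromosomes.
#' SNPs monomorphic in either sample are flagged so the polymorphic-in-both
#' filter can act on them.
#'
#' With `F = 0` a population's frequency equals the ancestral frequency
#' exactly (no-drift limit).
#'
#' @param config A [sim_config()]; uses `n_snps`, `n_diploids`,
#'   `divergence_F` and `rng_seed`.
#' @return A tibble with one row per SNP: `snp_id`, `p_anc`, `p1`, `p2`
#'   (population frequencies), `count1`, `count2`, `freq1`, `freq2`
#'   (sample counts and frequencies), `n_chrom`, and `poly_both`.
#' @export
simulate_divergence_freqs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  m <- config$n_snps
  n_chrom <- 2L * config$n_sample
  p_anc <- runif(m, 0.05, 0.95)
  draw_pop <- function(F) {
    if (F == 0) return(p_anc)
    a <- p_anc * (1 - F) / F
    b <- (1 - p_anc) * (1 - F) / F
    rbeta(m, a, b)
  }
  p1 <- draw_pop(config$divergence_F[1])
  p2 <- draw_pop(config$divergence_F[2])
  count1 <- rbinom(m, n_chrom, p1)
  count2 <- rbinom(m, n_chrom, p2)
  tibble(
    snp_id = sprintf("snp%05d", seq_len(m)),
    p_anc = p_anc, p1 = p1, p2 = p2,
    count1 = count1, count2 = count2,
    freq1 = count1 / n_chrom, freq2 = count2 / n_chrom,
    n_chrom = n_chrom,
    poly_both = count1 > 0 & count1 < n_chrom & count2 > 0 & count2 < n_chrom
  )
}
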