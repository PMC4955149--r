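#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' object so a fixture is fully reproducible from its config and seed.
#'
#' The defaults define the study conditions used throughout the package's
#' tests: two Wright-Fisher populations of 1000 diploids whose founder
#' pools (`K = 200` mosaic haplotypes) diverge under a Balding-Nichols
#' model with F = 0.05, followed by
#' 30 generations of independent drift with recombination; 50 diploids per
#' population are sampled at 1500 SNPs on a 2 Mb chromosome under a flat
#' 3 cM/Mb map (a 6 cM map, long relative to the ~1-2 cM footprint of the
#' sweeps simulated here, so haplotype homozygosity can decay to baseline
#' within the chromosome).
#'
#' @param n_diploids Diploid individuals per Wright-Fisher population
#'   (the effective population size of the forward simulation).
#' @param n_sample Diploid individuals sampled per population for the
#'   output panel (and for binomial allele counts in the frequency
#'   generator); capped at `n_diploids`.
#' @param n_snps Total number of biallelic SNPs, split evenly across
#'   chromosomes.
#' @param n_chromosomes Number of independently simulated chromosomes;
#'   the sweep, if any, is placed on the first.
#' @param chromosome_length Length of each chromosome in bp.
#' @param recomb_rate Recombination rate in cM/Mb; either a single number
#'   (flat map) or a data frame with `start`, `end` (bp) and `rate` columns
#'   for a piecewise-constant map covering the chromosome.
#' @param divergence_F Per-population differentiation coefficients in
#'   `[0, 1)` for the Balding-Nichols frequency generator; length 2.
#' @param sweep_site SNP index (1-based, within the first chromosome) of
#'   the selected site, or `NA` for a neutral simulation.
#' @param s Additive selection coefficient (>= 0); genotype fitnesses are
#'   1, 1+s, 1+2s.
#' @param sweep_mode `"hard"` (run to fixation from a single new copy) or
#'   `"incomplete"` (selection on standing variation, stop when the derived
#'   frequency first reaches `sweep_target`).
#' @param sweep_target Target derived frequency in `(0, 1]` for
#'   `sweep_mode = "incomplete"`.
#' @param sweep_start_freq Initial derived frequency at the sweep site for
#'   incomplete sweeps (standing variation); hard sweeps always start from
#'   a single copy.
#' @param n_generations Generations of Wright-Fisher drift after the
#'   population split (and the nominal sweep duration; hard sweeps may run
#'   up to 10x this cap before the attempt is abandoned and retried).
#' @param founder_haplotypes Number `K` of distinct founder haplotypes from
#'   which the initial populations are built as recombinant mosaics. `K`
#'   must be large enough that founder-pool sampling variance, p(1-p)/2K,
#'   stays small against the Balding-Nichols variance F p(1-p): small
#'   pools both inflate realized differentiation beyond the configured F
#'   and create drifted haplotype blocks that mimic selective sweeps.
#' @param founder_segment_cm Expected mosaic segment length (cM) in founder
#'   haplotype construction; controls the baseline LD decay scale.
#' @param retry_cap Maximum restart attempts when the sweep allele is lost.
#' @param rng_seed Integer seed; the same config and seed give bit-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_diploids = 1000, n_sample = 50, n_snps = 1500,
                       n_chromosomes = 1, chromosome_length = 2e6,
                       recomb_rate = 3,
                       divergence_F = c(0.05, 0.05),
                       sweep_site = NA_integer_, s = 0,
                       sweep_mode = c("hard", "incomplete"),
                       sweep_target = 0.5, sweep_start_freq = 0.05,
                       n_generations = 30, founder_haplotypes = 200,
                       founder_segment_cm = 0.05, retry_cap = 100,
                       rng_seed = 1L) {
  sweep_mode <- match.arg(sweep_mode)
  if (any(divergence_F < 0) || any(divergence_F >= 1)) {
    abort("divergence_F must lie in [0, 1); F = 1 is degenerate")
  }
  if (s < 0) abort("selection coefficient s must be >= 0")
  if (sweep_target <= 0 || sweep_target > 1) {
    abort("sweep_target must lie in (0, 1]")
  }
  if (n_snps < 1) abort("n_snps must be >= 1")
  snps_per_chrom <- as.integer(n_snps %/% n_chromosomes)
  if (!is.na(sweep_site) && (sweep_site < 1 || sweep_site > snps_per_chrom)) {
    abort("sweep_site must be a SNP index within the first chromosome")
  }
  if (founder_haplotypes < 2) abort("founder_haplotypes K must be >= 2")
  structure(
    list(
      n_diploids = as.integer(n_diploids),
      n_sample = as.integer(min(n_sample, n_diploids)),
      n_snps = as.integer(n_snps),
      n_chromosomes = as.integer(n_chromosomes),
      snps_per_chrom = snps_per_chrom,
      chromosome_length = chromosome_length, recomb_rate = recomb_rate,
      divergence_F = divergence_F, sweep_site = sweep_site, s = s,
      sweep_mode = sweep_mode, sweep_target = sweep_target,
      sweep_start_freq = sweep_start_freq,
      n_generations = as.integer(n_generations),
      founder_haplotypes = as.integer(founder_haplotypes),
      founder_segment_cm = founder_segment_cm,
      retry_cap = as.integer(retry_cap), rng_seed = as.integer(rng_seed)
    ),
    class = "sim_config"
  )
}

# SNP positions and cumulative genetic map for one chromosome of a config.
# Positions are drawn without replacement then sorted, so they are strictly
# increasing; the map is piecewise linear in bp.
config_coordinates <- function(config, chrom_index = 1L) {
  n <- config$snps_per_chrom
  pos <- sort(sample.int(config$chromosome_length - 2L, n)) + 1L
  if (is.data.frame(config$recomb_rate)) {
    seg <- config$recomb_rate
    bounds <- c(seg$start[1], seg$end)
    cum <- c(0, cumsum((seg$end - seg$start) / 1e6 * seg$rate))
    cm <- approx(bounds, cum, xout = pos, rule = 2)$y
  } else {
    cm <- pos / 1e6 * config$recomb_rate
  }
  tibble(
    snp_id = sprintf("c%d_snp%05d", chrom_index, seq_len(n)),
    chrom = paste0("chr", chrom_index), pos = pos, cm = cm
  )
}
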