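# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, enumeration) and never call the code paths they check.

# random small phased panel with strictly increasing positions
make_test_panel <- function(n_hap = 10, n_snp = 20, seed = 1,
                            pos = NULL, cm = NULL, chrom = "chr1",
                            population = "popA") {
  set.seed(seed)
  H <- matrix(rbinom(n_hap * n_snp, 1L, 0.5), n_hap, n_snp)
  if (is.null(pos)) pos <- sort(sample.int(n_snp * 1000L, n_snp))
  if (is.null(cm)) cm <- pos / 1e6
  n_ind <- ceiling(n_hap / 2)
  hap_of <- rep(seq_len(n_ind), each = 2)[seq_len(n_hap)]
  haplotype_panel(
    H,
    tibble::tibble(snp_id = sprintf("s%03d", seq_len(n_snp)),
                   chrom = chrom, pos = pos, cm = cm),
    tibble::tibble(hap_id = sprintf("h%02d", seq_len(n_hap)),
                   sample_id = sprintf("i%02d", hap_of),
                   population = population)
  )
}

# a panel built from an explicit haplotype matrix
panel_from_matrix <- function(H, pos, cm = pos / 1e6, population = "popA") {
  make <- make_test_panel(nrow(H), ncol(H), seed = 1, pos = pos, cm = cm,
                          population = population)
  haplotype_panel(H, make$snps, make$samples)
}

# EHH by brute-force pairwise comparison of carrier haplotypes over the
# span focal..j (inclusive)
ehh_oracle <- function(H, focal, j, core_allele) {
  carriers <- which(H[, focal] == core_allele)
  cols <- seq(min(focal, j), max(focal, j))
  n <- length(carriers)
  same <- 0L
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (all(H[carriers[a], cols] == H[carriers[b], cols])) same <- same + 1L
    }
  }
  same / (n * (n - 1) / 2)
}

# trapezoid rule written out longhand
trapezoid_oracle <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# SNP-in-gene assignment by double loop over all (snp, gene) pairs
assign_oracle <- function(snp_positions, gene_unions) {
  out <- list()
  for (i in seq_len(nrow(snp_positions))) {
    for (j in seq_len(nrow(gene_unions))) {
      if (snp_positions$chrom[i] == gene_unions$chrom[j] &&
          snp_positions$pos[i] >= gene_unions$start[j] &&
          snp_positions$pos[i] <= gene_unions$end[j]) {
        out[[length(out) + 1]] <- c(snp_positions$snp_id[i],
                                    gene_unions$gene_id[j])
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(snp_id = character(0), gene_id = character(0)))
  }
  m <- do.call(rbind, out)
  tibble::tibble(snp_id = m[, 1], gene_id = m[, 2])
}

# mixture density by quadrature: truncated-normal normalizer computed by
# numerical integration rather than pnorm
mixture_density_oracle <- function(p1, p2, omega, c_esc) {
  sdv <- sqrt(omega * p2 * (1 - p2))
  z_norm <- stats::integrate(function(z) stats::dnorm(z, p2, sdv), 0, 1,
                             rel.tol = 1e-10)$value
  branch <- function(z) {
    if (z <= 0 || z >= 1) return(0)
    stats::dnorm(z, p2, sdv) / z_norm
  }
  (p2 * branch((p1 - (1 - c_esc)) / c_esc) +
     (1 - p2) * branch(p1 / c_esc)) / c_esc
}

# small annotated dataset reused by enrichment and pipeline tests:
# sweep planted mid-chromosome inside the "planted" gene set
make_sweep_dataset <- function(seed = 1, s = 0.1, mode = "hard", ...) {
  dots <- list(...)
  n_snps <- if (!is.null(dots$n_snps)) dots$n_snps else 1500
  cfg <- do.call(sim_config, c(
    list(sweep_site = floor(n_snps / 2), s = s, sweep_mode = mode,
         rng_seed = seed), dots))
  sim <- simulate_sweep_panel(cfg)
  bundle <- generate_annotation_bundle(cfg, sim)
  list(cfg = cfg, sim = sim, bundle = bundle)
}
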