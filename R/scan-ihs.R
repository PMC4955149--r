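#' Extended haplotype homozygosity decay from a focal SNP
#'
#' Among the haplotypes carrying `core_allele` at the focal SNP, EHH at a
#' flanking SNP x is the probability that two randomly drawn carriers are
#' identical over the whole stretch focal..x:
#' `EHH = sum_h C(n_h, 2) / C(n, 2)` over the distinct extended haplotypes
#' h. The curve starts at EHH = 1 at distance 0, is non-increasing, and is
#' extended while EHH >= `threshold`; it stops at (and includes) the first
#' SNP where EHH drops below the threshold. Extension also stops, with the
#' corresponding termination code, at the chromosome end or when the
#' physical gap to the next SNP exceeds `gap_bp` (200 kb).
#'
#' @param panel A [haplotype_panel()] (single chromosome).
#' @param focal Focal SNP: index or `snp_id`.
#' @param core_allele 0 (ancestral) or 1 (derived).
#' @param direction `"left"` or `"right"`.
#' @param threshold EHH stopping value (default 0.05).
#' @param gap_bp Maximum tolerated gap between consecutive SNPs (bp).
#' @return An `ehh_curve`: tibble with `snp_id`, `distance_cm` (genetic
#'   distance from the focal SNP) and `ehh`, with attributes `termination`
#'   (`"threshold_reached"`, `"chromosome_end"` or `"gap"`), `direction`,
#'   `focal` and `core_allele`.
#' @export
compute_ehh <- function(panel, focal, core_allele, direction = c("right", "left"),
                        threshold = 0.05, gap_bp = 2e5) {
  direction <- match.arg(direction)
  j0 <- if (is.character(focal)) match(focal, panel$snps$snp_id) else focal
  if (is.na(j0) || j0 < 1 || j0 > nrow(panel$snps)) abort("focal SNP not found")
  carriers <- which(panel$haplotypes[, j0] == core_allele)
  n <- length(carriers)
  if (n < 2) {
    abort(sprintf("EHH undefined: %d haplotype(s) carry allele %d at the focal SNP",
                  n, core_allele))
  }
  step <- if (direction == "right") 1L else -1L
  denom <- n_pairs(n)
  cm0 <- panel$snps$cm[j0]
  H <- panel$haplotypes

  kept <- j0
  ehh <- 1
  grp <- rep(1L, n)
  n_grp <- 1L
  termination <- "chromosome_end"
  j <- j0
  repeat {
    nxt <- j + step
    if (nxt < 1L || nxt > ncol(H) ||
        panel$snps$chrom[nxt] != panel$snps$chrom[j]) {
      termination <- "chromosome_end"; break
    }
    if (abs(panel$snps$pos[nxt] - panel$snps$pos[j]) > gap_bp) {
      termination <- "gap"; break
    }
    j <- nxt
    # refine the grouping of carriers by the allele at the new SNP;
    # group codes stay <= 2 * n + 1 so tabulate() replaces hashing
    code <- grp * 2L + H[carriers, j]
    cnt <- tabulate(code, nbins = 2L * n_grp + 1L)
    e <- sum(n_pairs(cnt)) / denom
    nz <- which(cnt > 0L)
    lookup <- integer(2L * n_grp + 1L)
    lookup[nz] <- seq_along(nz)
    grp <- lookup[code]
    n_grp <- length(nz)
    kept <- c(kept, j)
    ehh <- c(ehh, e)
    if (e < threshold) { termination <- "threshold_reached"; break }
  }
  ids <- panel$snps$snp_id[kept]
  dist <- abs(panel$snps$cm[kept] - cm0)
  structure(
    tibble(snp_id = ids, distance_cm = dist, ehh = ehh),
    termination = termination, direction = direction,
    focal = panel$snps$snp_id[j0], core_allele = core_allele,
    class = c("ehh_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Integrated haplotype homozygosity of an EHH curve
#'
#' Trapezoidal integral of EHH against genetic distance, from the focal
#' SNP up to and including the first point below the stopping threshold.
#' When the curve terminated at the chromosome end or at a gap the
#' statistic cannot be calculated and `NA` is returned with the reason;
#' a degenerate single-point or zero-length curve is likewise undefined.
#'
#' @param curve An `ehh_curve` from [compute_ehh()].
#' @return A list with `ihh` (cM, or `NA`) and `reason` (`NA` when
#'   defined; otherwise `"chromosome_end"`, `"gap"` or `"zero_area"`).
#' @export
compute_ihh <- function(curve) {
  term <- attr(curve, "termination")
  if (term != "threshold_reached") {
    return(list(ihh = NA_real_, reason = term))
  }
  if (nrow(curve) < 2) return(list(ihh = NA_real_, reason = "zero_area"))
  d <- curve$distance_cm
  e <- curve$ehh
  area <- sum(diff(d) * (head(e, -1) + tail(e, -1)) / 2)
  if (area <= 0) return(list(ihh = NA_real_, reason = "zero_area"))
  list(ihh = area, reason = NA_character_)
}

#' Genome scan of the integrated haplotype score (iHS)
#'
#' For every SNP with minor-allele frequency at least `maf_min`, the EHH
#' decay is integrated left and right of the focal SNP separately for the
#' ancestral- and derived-allele carriers; `iHH` per allele is the sum of
#' the two directional integrals and the raw score is
#' `iHS = ln(iHH_ancestral / iHH_derived)`. Raw scores are standardized to
#' mean 0 and unit variance within derived-allele-frequency bins
#' (`n_bins` equal-width bins on (0,1); bins with fewer than two defined
#' scores, or zero spread, are merged into their left neighbour and the
#' merges reported). SNPs where any of the four EHH integrals is undefined
#' (chromosome end, >200 kb gap, fewer than two carriers of an allele) are
#' flagged with the reason and excluded from the bin moments.
#'
#' @param panel A [haplotype_panel()]; typically one population
#'   ([panel_population()]).
#' @param maf_min Minor-allele-frequency floor (default 0.05).
#' @param n_bins Number of derived-frequency bins for standardization.
#' @param threshold,gap_bp Passed to [compute_ehh()].
#' @return An `ihs_scan` object whose `scores` tibble has one row per
#'   scanned SNP: `snp_id`, `chrom`, `pos`, `freq_derived`, `ihh_a`,
#'   `ihh_d`, `raw_ihs`, `std_ihs`, `defined`, `reason`, `bin`.
#' @export
ihs_scan <- function(panel, maf_min = 0.05, n_bins = 20,
                     threshold = 0.05, gap_bp = 2e5) {
  H <- panel$haplotypes
  n_hap <- nrow(H)
  freq <- colMeans(H)
  maf <- pmin(freq, 1 - freq)
  scan_idx <- which(maf >= maf_min)
  if (!length(scan_idx)) abort("no SNPs pass the MAF filter")

  one_side <- function(j, allele, dir) {
    if (sum(H[, j] == allele) < 2) {
      return(list(ihh = NA_real_, reason = "too_few_carriers"))
    }
    compute_ihh(compute_ehh(panel, j, allele, dir,
                            threshold = threshold, gap_bp = gap_bp))
  }
  res <- purrr::map(scan_idx, function(j) {
    parts <- list(
      one_side(j, 0L, "left"), one_side(j, 0L, "right"),
      one_side(j, 1L, "left"), one_side(j, 1L, "right")
    )
    ihh_a <- parts[[1]]$ihh + parts[[2]]$ihh
    ihh_d <- parts[[3]]$ihh + parts[[4]]$ihh
    reason <- purrr::map_chr(parts, "reason") |> (\(r) r[!is.na(r)])()
    tibble(
      snp_id = panel$snps$snp_id[j], chrom = panel$snps$chrom[j],
      pos = panel$snps$pos[j], freq_derived = freq[j],
      ihh_a = ihh_a, ihh_d = ihh_d,
      raw_ihs = if (!is.na(ihh_a) && !is.na(ihh_d)) log(ihh_a / ihh_d) else NA_real_,
      defined = !is.na(ihh_a) && !is.na(ihh_d),
      reason = if (length(reason)) paste(unique(reason), collapse = ";")
               else NA_character_
    )
  }) |> purrr::list_rbind()

  std <- standardize_by_bins(res$raw_ihs, res$freq_derived, n_bins)
  res$std_ihs <- std$z
  res$bin <- std$bin
  structure(
    list(scores = res,
         params = list(maf_min = maf_min, n_bins = n_bins,
                       threshold = threshold, gap_bp = gap_bp,
                       n_haplotypes = n_hap, bin_merges = std$merges),
         method = "ihs"),
    class = c("ihs_scan", "sweep_scan")
  )
}

# z-score x within equal-width frequency bins; small or degenerate bins
# are merged leftwards (rightwards for the leftmost bin)
standardize_by_bins <- function(x, freq, n_bins) {
  bin <- pmin(pmax(ceiling(freq * n_bins), 1L), n_bins)
  merges <- 0L
  repeat {
    ok <- TRUE
    for (b in sort(unique(bin))) {
      v <- x[bin == b]
      v <- v[!is.na(v)]
      if (length(v) < 2 || sd(v) < 1e-12) {
        others <- setdiff(sort(unique(bin)), b)
        if (!length(others)) break
        left <- others[others < b]
        tgt <- if (length(left)) max(left) else min(others)
        bin[bin == b] <- tgt
        merges <- merges + 1L
        ok <- FALSE
        break
      }
    }
    if (ok) break
  }
  z <- rep(NA_real_, length(x))
  for (b in unique(bin)) {
    i <- which(bin == b & !is.na(x))
    if (length(i) >= 2) z[i] <- (x[i] - mean(x[i])) / sd(x[i])
  }
  list(z = z, bin = bin, merges = merges)
}
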