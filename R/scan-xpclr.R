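#' Keep SNPs polymorphic in both populations
#'
#' The composite-likelihood scan's false-discovery rate rises sharply once
#' a SNP is fixed in either sample, so only SNPs with sample frequency
#' strictly between 0 and 1 in both populations are scanned.
#'
#' @param freqs A data frame with `snp_id`, `freq1` (objective) and
#'   `freq2` (reference) sample frequencies.
#' @return The retained rows, as a tibble.
#' @export
polymorphic_filter <- function(freqs) {
  out <- filter(as_tibble(freqs),
                .data$freq1 > 0, .data$freq1 < 1,
                .data$freq2 > 0, .data$freq2 < 1)
  if (!nrow(out)) abort("no SNP is polymorphic in both populations; nothing to scan")
  out
}

#' Method-of-moments drift coefficient between two populations
#'
#' `omega = mean((p1 - p2)^2 / (p2 (1 - p2)))` over retained SNPs, floored
#' at `floor` to keep the drift kernel proper when the populations are
#' essentially undifferentiated. Under a Balding-Nichols model with
#' differentiation F in each population its expectation is approximately
#' 2F (each population contributes variance F p(1-p) around the shared
#' ancestral frequency).
#'
#' @param freqs Data frame with `freq1` (objective) and `freq2`
#'   (reference), already restricted to polymorphic-in-both SNPs.
#' @param floor Lower bound for the estimate.
#' @return The scalar drift coefficient estimate.
#' @export
estimate_drift <- function(freqs, floor = 1e-4) {
  p1 <- freqs$freq1
  p2 <- freqs$freq2
  if (!length(p1)) abort("no SNPs to estimate drift from")
  max(floor, mean((p1 - p2)^2 / (p2 * (1 - p2))))
}

#' Sweep-model density of objective-population frequencies
#'
#' Density of the objective frequency `p1` given the reference frequency
#' `p2` under the drift + sweep mixture model. Neutral drift is a Normal
#' kernel `Z ~ N(p2, omega p2 (1 - p2))` truncated to (0, 1) and
#' renormalized. A sweep at recombination distance `r` (Morgans) from the
#' site lets a lineage escape the sweep with probability
#' `c = 1 - exp(-r / q)` where `q` is the sweep scale (`c = 1` when
#' `q = 0`, collapsing to neutrality): with probability `p2` the favoured
#' background carries the allele and `p1 = (1 - c) + c Z`, otherwise
#' `p1 = c Z`.
#'
#' @param p1 Objective-population frequency (vectorized).
#' @param p2 Reference-population frequency (vectorized with `p1`).
#' @param omega Drift coefficient.
#' @param c_esc Escape probability in `[0, 1]` (vectorized with `p1`).
#' @return The mixture density at `p1` (0 outside the support; for
#'   `c_esc = 0` the distribution is purely boundary mass, so interior
#'   density is 0).
#' @export
sweep_mixture_density <- function(p1, p2, omega, c_esc) {
  n <- max(length(p1), length(p2), length(c_esc))
  p1 <- rep_len(p1, n)
  p2 <- rep_len(p2, n)
  c_esc <- rep_len(as.vector(c_esc), n)
  sdv <- sqrt(omega * p2 * (1 - p2))
  z_norm <- pnorm(1, p2, sdv) - pnorm(0, p2, sdv)
  tn <- function(z) ifelse(z > 0 & z < 1, dnorm(z, p2, sdv) / z_norm, 0)
  ifelse(c_esc <= 0, 0,
         (p2 * tn((p1 - (1 - c_esc)) / c_esc) +
            (1 - p2) * tn(p1 / c_esc)) / c_esc)
}

#' Weighted log composite likelihood of a SNP window
#'
#' Sum over window SNPs of `w_k * ln f(p1_k | p2_k, omega, q)` with the
#' sweep-mixture density at escape probability
#' `c_k = 1 - exp(-r_k / q)`; `q = 0` gives the neutral likelihood
#' exactly. Per-SNP log densities are floored at `log_floor` (underflows
#' are counted in the `"n_floored"` attribute).
#'
#' @param p1,p2 Objective / reference frequencies of the window SNPs.
#' @param r Recombination distances (Morgans, >= 0) from each SNP to the
#'   grid point.
#' @param omega Drift coefficient.
#' @param q Sweep scale (Morgans, >= 0).
#' @param w Per-SNP composite-likelihood weights (default 1).
#' @param log_floor Per-SNP floor on the log density.
#' @return Weighted log composite likelihood (scalar).
#' @export
window_composite_loglik <- function(p1, p2, r, omega, q,
                                    w = rep(1, length(p1)),
                                    log_floor = -50) {
  stopifnot(q >= 0, all(r >= 0))
  c_esc <- if (q == 0) rep(1, length(p1)) else 1 - exp(-r / q)
  f <- sweep_mixture_density(p1, p2, omega, c_esc)
  lf <- ifelse(f > 0, log(f), -Inf)
  floored <- lf < log_floor
  lf[floored] <- log_floor
  structure(sum(w * lf), n_floored = sum(floored))
}

#' Cross-population composite-likelihood-ratio scan
#'
#' Scans a physical grid (default spacing 200 bp) along each chromosome.
#' The window at a grid point holds the nearest `window_snps` retained
#' SNPs (half per side where available, fewer near chromosome ends). Each
#' window SNP k carries weight `w_k = 1 / m_k`, where `m_k` counts window
#' SNPs (including k) whose r-squared with k in the reference panel is at
#' least `r2_threshold`, down-weighting redundant tightly linked sites.
#' The grid score is `2 * (max over q in Q of the weighted sweep
#' log-likelihood - the neutral log-likelihood)`; since `0` is in `Q` the
#' score is non-negative. Each SNP inherits the score of its nearest grid
#' point (ties toward the lower coordinate) and SNP scores are then
#' normalized genome-wide to mean 0, unit variance.
#'
#' @param freqs Data frame with `snp_id`, `freq1` (objective), `freq2`
#'   (reference); the polymorphic-in-both filter is applied internally.
#' @param panel Reference-population [haplotype_panel()] supplying SNP
#'   coordinates and the haplotypes for the LD weights.
#' @param spacing Grid spacing in bp.
#' @param window_snps SNPs per window.
#' @param q_grid Sweep-scale grid in Morgans; must contain 0. Default
#'   `{0} + 15` log-spaced points from 1e-6 to 0.1.
#' @param omega Drift coefficient; `NULL` (default) estimates it with
#'   [estimate_drift()].
#' @param omega_floor Floor for the drift estimate.
#' @param r2_threshold r-squared threshold for the LD down-weighting.
#' @param log_floor Per-SNP log-density floor.
#' @return An `xpclr_scan` object: `grid` tibble (`chrom`, `grid_pos`,
#'   `q_hat`, `score`, `n_snps`), `scores` tibble (`snp_id`, `chrom`,
#'   `pos`, `freq1`, `freq2`, `raw_score`, `std_score`), and `params`.
#' @export
xpclr_scan <- function(freqs, panel, spacing = 200, window_snps = 50,
                       q_grid = NULL, omega = NULL, omega_floor = 1e-4,
                       r2_threshold = 0.95, log_floor = -50) {
  q_grid <- q_grid %||% c(0, 10^seq(log10(1e-6), log10(0.1), length.out = 15))
  if (!any(q_grid == 0)) abort("q_grid must contain 0 (the neutral model)")
  stopifnot(spacing > 0, window_snps >= 1)

  retained <- polymorphic_filter(freqs)
  idx <- match(retained$snp_id, panel$snps$snp_id)
  if (anyNA(idx)) abort("frequency table contains SNPs absent from the panel")
  ord <- order(panel$snps$chrom[idx], panel$snps$pos[idx])
  retained <- retained[ord, ]
  idx <- idx[ord]
  snp <- panel$snps[idx, ]
  H <- panel$haplotypes[, idx, drop = FALSE]
  omega <- omega %||% estimate_drift(retained, floor = omega_floor)

  half <- window_snps %/% 2L
  grid_out <- list()
  snp_raw <- rep(NA_real_, nrow(retained))

  for (ch in unique(snp$chrom)) {
    ci <- which(snp$chrom == ch)
    pos <- snp$pos[ci]
    cm <- snp$cm[ci]
    grid <- seq(min(pos), max(pos), by = spacing)
    n <- length(ci)

    # window of a grid point: `half` SNPs per side (fewer at the ends)
    right_of <- findInterval(grid, pos + 0.5) + 1L  # first SNP index > grid
    lo <- pmax(1L, right_of - half)
    hi <- pmin(n, right_of + half - 1L)

    # LD weights per distinct window (windows are contiguous SNP runs)
    wkey <- paste(lo, hi)
    w_cache <- new.env(parent = emptyenv())
    get_weights <- function(l, h) {
      key <- paste(l, h)
      if (!is.null(w_cache[[key]])) return(w_cache[[key]])
      block <- H[, ci[l:h], drop = FALSE]
      r2 <- suppressWarnings(stats::cor(block))^2
      r2[is.na(r2)] <- 1  # zero-variance columns cannot arise post-filter
      w <- 1 / rowSums(r2 >= r2_threshold)
      w_cache[[key]] <- w
      w
    }

    g_scores <- rep(NA_real_, length(grid))
    g_qhat <- rep(NA_real_, length(grid))
    g_n <- hi - lo + 1L
    grid_cm <- approx(pos, cm, xout = grid, rule = 2)$y
    # all q evaluated at once per grid point: SNP x q matrices
    nq <- length(q_grid)
    qpos <- q_grid[q_grid > 0]
    for (g in seq_along(grid)) {
      if (g_n[g] < 2L) next  # skipped, too few SNPs
      k <- lo[g]:hi[g]
      w <- get_weights(lo[g], hi[g])
      p1 <- retained$freq1[ci[k]]
      p2 <- retained$freq2[ci[k]]
      r <- abs(cm[k] - grid_cm[g]) / 100
      c_esc <- cbind(1, 1 - exp(-outer(r, qpos, "/")))
      f <- sweep_mixture_density(rep(p1, nq), rep(p2, nq), omega, c_esc)
      lf <- matrix(pmax(ifelse(f > 0, log(f), -Inf), log_floor), ncol = nq)
      ll <- colSums(w * lf)
      best <- which.max(ll)
      g_scores[g] <- 2 * (ll[best] - ll[1])
      g_qhat[g] <- c(0, qpos)[best]
    }
    grid_out[[ch]] <- tibble(chrom = ch, grid_pos = grid, q_hat = g_qhat,
                             score = g_scores, n_snps = g_n)

    # SNP score = nearest scored grid point (ties toward lower coordinate)
    scored <- which(!is.na(g_scores))
    if (length(scored)) {
      gp <- grid[scored]
      nearest <- vapply(pos, function(p) {
        d <- abs(gp - p)
        scored[which(d == min(d))[1]]
      }, integer(1))
      snp_raw[ci] <- g_scores[nearest]
    }
  }

  grid_tbl <- purrr::list_rbind(grid_out)
  std <- (snp_raw - mean(snp_raw, na.rm = TRUE)) / sd(snp_raw, na.rm = TRUE)
  scores <- tibble(
    snp_id = retained$snp_id, chrom = snp$chrom, pos = snp$pos,
    freq1 = retained$freq1, freq2 = retained$freq2,
    raw_score = snp_raw, std_score = std
  )
  structure(
    list(grid = grid_tbl, scores = scores,
         params = list(spacing = spacing, window_snps = window_snps,
                       q_grid = q_grid, omega = omega,
                       r2_threshold = r2_threshold, log_floor = log_floor,
                       n_retained = nrow(retained),
                       n_skipped_grid = sum(is.na(grid_tbl$score))),
         method = "xpclr"),
    class = c("xpclr_scan", "sweep_scan")
  )
}
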