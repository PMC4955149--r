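#' Simulate a phased haplotype panel with an optional planted sweep
#'
#' Forward diploid Wright-Fisher simulation with random mating, additive
#' selection at a single site (fitnesses 1, 1+s, 1+2s) and per-generation
#' Poisson crossovers placed on the genetic map. Population divergence
#' follows the same Balding-Nichols model as
#' [simulate_divergence_freqs()]: each population's founder haplotype pool
#' is drawn around shared ancestral frequencies with its own
#' differentiation coefficient F, so allele-frequency divergence is set by
#' `divergence_F` rather than by long drift, and the Wright-Fisher phase
#' stays short enough to preserve haplotype diversity (the extended
#' haplotype homozygosity of a neutral site must be able to decay below
#' the iHS stopping value within the chromosome). Founders are recombinant
#' mosaics of `K` random binary haplotypes, giving LD that decays on the
#' cM scale; selection acts in population 1 only.
#'
#' Sweep modes: `"hard"` seeds a single derived copy in population 1 and
#' runs until it fixes (attempts where it is lost, or where fixation takes
#' more than 10x `n_generations`, are restarted with an incremented seed up
#' to `retry_cap` times); `"incomplete"` seeds standing variation at
#' `sweep_start_freq` in both populations and stops the first generation
#' the derived frequency reaches `sweep_target`. With `s = 0` the site is
#' merely tracked and the run lasts exactly `n_generations` (the neutral
#' martingale case). Both populations are always sampled at the same
#' generation.
#'
#' @param config A [sim_config()].
#' @return An object of class `sweep_sim`: a list with `panel` (a
#'   [haplotype_panel()] holding both populations), `sweep` (one-row tibble
#'   of the true sweep record: site, mode, s, final frequencies,
#'   generations run, attempts used) and `trajectory` (per-generation
#'   derived frequency at the sweep site in population 1).
#' @export
simulate_sweep_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  has_sweep <- !is.na(config$sweep_site)
  selected <- has_sweep && config$s > 0

  for (attempt in seq_len(max(1L, config$retry_cap))) {
    # widely separated retry streams: distinct base seeds must never share
    # an effective seed, whatever attempt first succeeds
    set.seed(derive_seed(config$rng_seed, sprintf("attempt%03d", attempt)))

    # chromosome 1 (carrying any sweep) decides the run length; further
    # chromosomes evolve neutrally and independently for as long
    snps_list <- list()
    hap1_list <- list()
    hap2_list <- list()
    generations <- NA_integer_
    lost <- FALSE
    for (ch in seq_len(config$n_chromosomes)) {
      snps <- config_coordinates(config, ch)
      p_anc <- runif(config$snps_per_chrom, 0.05, 0.95)
      pop1 <- founder_mosaics(make_founders(config, p_anc, config$divergence_F[1]),
                              snps$cm, 2L * config$n_diploids,
                              config$founder_segment_cm)
      pop2 <- founder_mosaics(make_founders(config, p_anc, config$divergence_F[2]),
                              snps$cm, 2L * config$n_diploids,
                              config$founder_segment_cm)
      sweep_here <- has_sweep && ch == 1L
      if (sweep_here) {
        site <- config$sweep_site
        n_chrom <- 2L * config$n_diploids
        if (config$sweep_mode == "hard" && config$s > 0) {
          pop1[, site] <- 0L
          pop1[sample.int(n_chrom, 1L), site] <- 1L
          pop2[, site] <- 0L
        } else {
          k <- max(1L, round(config$sweep_start_freq * n_chrom))
          for (mat in c("pop1", "pop2")) {
            m <- get(mat)
            m[, site] <- 0L
            m[sample.int(n_chrom, k), site] <- 1L
            assign(mat, m)
          }
        }
      }

      if (ch == 1L) {
        res1 <- wf_evolve(pop1, snps$cm, config,
                          site = if (sweep_here) config$sweep_site else NA,
                          s = config$s,
                          mode = if (selected) config$sweep_mode else "neutral",
                          target = config$sweep_target)
        if (!res1$ok) { lost <- TRUE; break }
        generations <- res1$generations
        traj <- res1$trajectory
      } else {
        res1 <- wf_evolve(pop1, snps$cm, config, site = NA, s = 0,
                          mode = "fixed_length", n_gen = generations)
      }
      res2 <- wf_evolve(pop2, snps$cm, config, site = NA, s = 0,
                        mode = "fixed_length", n_gen = generations)

      # sample n_sample diploids (both chromosomes of each) per population
      n <- config$n_sample
      take <- function(mat) {
        ind <- sort(sample.int(config$n_diploids, n))
        mat[as.vector(rbind(2L * ind - 1L, 2L * ind)), , drop = FALSE]
      }
      snps_list[[ch]] <- snps
      hap1_list[[ch]] <- take(res1$haplotypes)
      hap2_list[[ch]] <- take(res2$haplotypes)
    }
    if (lost) next  # sweep allele lost or stalled: retry, new seed

    snps <- dplyr::bind_rows(snps_list)
    hap1 <- do.call(cbind, hap1_list)
    hap2 <- do.call(cbind, hap2_list)
    n <- config$n_sample
    samples <- tibble(
      hap_id = sprintf("%s_i%03d_h%d", rep(c("pop1", "pop2"), each = 2L * n),
                       rep(rep(seq_len(n), each = 2L), 2L), rep(1:2, 2L * n)),
      sample_id = sprintf("%s_i%03d", rep(c("pop1", "pop2"), each = 2L * n),
                          rep(rep(seq_len(n), each = 2L), 2L)),
      population = rep(c("pop1", "pop2"), each = 2L * n)
    )
    panel <- haplotype_panel(rbind(hap1, hap2), snps, samples)
    sweep <- tibble(
      sweep_site = if (has_sweep) config$sweep_site else NA_integer_,
      sweep_pos = if (has_sweep) snps$pos[config$sweep_site] else NA_integer_,
      sweep_chrom = if (has_sweep) snps$chrom[config$sweep_site] else NA_character_,
      sweep_mode = if (selected) config$sweep_mode else "neutral",
      s = config$s,
      final_freq_pop1 = if (has_sweep) mean(hap1[, config$sweep_site]) else NA_real_,
      final_freq_pop2 = if (has_sweep) mean(hap2[, config$sweep_site]) else NA_real_,
      generations = generations, attempts = attempt
    )
    return(structure(
      list(panel = panel, sweep = sweep, trajectory = traj),
      class = "sweep_sim"
    ))
  }
  abort(sprintf(
    "sweep allele lost in all %d attempts (s = %g may be too weak to establish)",
    config$retry_cap, config$s
  ))
}

#' @export
print.sweep_sim <- function(x, ...) {
  cat("<sweep_sim>\n")
  print(x$panel)
  print(x$sweep)
  invisible(x)
}

# K binary founder haplotypes; population frequencies are Balding-Nichols
# draws with coefficient F around the shared ancestral frequencies p_anc
make_founders <- function(config, p_anc, F) {
  p <- if (F == 0) p_anc else {
    rbeta(length(p_anc), p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }
  matrix(rbinom(config$founder_haplotypes * length(p_anc), 1L,
                rep(p, each = config$founder_haplotypes)),
         nrow = config$founder_haplotypes)
}

# n_hap mosaics of the founder rows; segment boundaries are Poisson on the
# cM axis with expected segment length seg_cm
founder_mosaics <- function(founders, cm, n_hap, seg_cm) {
  total_cm <- max(cm) - min(cm)
  K <- nrow(founders)
  out <- matrix(0L, n_hap, length(cm))
  for (i in seq_len(n_hap)) {
    n_bk <- rpois(1L, total_cm / seg_cm)
    bounds <- sort(runif(n_bk, min(cm), max(cm)))
    seg <- findInterval(cm, bounds) + 1L
    src <- sample.int(K, n_bk + 1L, replace = TRUE)
    out[i, ] <- founders[cbind(src[seg], seq_along(cm))]
  }
  out
}

# One population's forward evolution. mode: "neutral" (run n_generations),
# "fixed_length" (run n_gen), "hard" (run to fixation, cap 10x
# n_generations), "incomplete" (stop when target first reached).
wf_evolve <- function(haps, cm, config, site, s, mode,
                      target = 1, n_gen = NULL) {
  n_chrom <- nrow(haps)
  n_ind <- n_chrom %/% 2L
  morgans <- (max(cm) - min(cm)) / 100
  max_gen <- switch(mode,
    neutral = config$n_generations,
    fixed_length = n_gen,
    hard = 10L * config$n_generations,
    incomplete = 10L * config$n_generations
  )
  traj <- numeric(0)
  gen <- 0L
  while (gen < max_gen) {
    gen <- gen + 1L
    w <- rep(1, n_ind)
    if (!is.na(site) && s > 0) {
      g <- haps[seq(1L, n_chrom, 2L), site] + haps[seq(2L, n_chrom, 2L), site]
      w <- 1 + s * g
    }
    parents <- sample.int(n_ind, n_chrom, replace = TRUE, prob = w)
    ncx <- rpois(n_chrom, morgans)
    first <- rbinom(n_chrom, 1L, 0.5)  # which parental chromatid leads
    chosen <- 2L * parents - 1L + first
    new <- haps[chosen, , drop = FALSE]
    for (i in which(ncx > 0L)) {
      bounds <- sort(runif(ncx[i], min(cm), max(cm)))
      use_second <- (findInterval(cm, bounds) + first[i]) %% 2L == 1L
      a <- haps[2L * parents[i] - 1L, ]
      b <- haps[2L * parents[i], ]
      new[i, ] <- ifelse(use_second, b, a)
    }
    haps <- new
    if (!is.na(site)) {
      f <- mean(haps[, site])
      traj <- c(traj, f)
      if (mode %in% c("hard", "incomplete") && f == 0) {
        return(list(ok = FALSE))
      }
      if (mode == "hard" && f == 1) {
        return(list(ok = TRUE, haplotypes = haps, generations = gen,
                    trajectory = traj))
      }
      if (mode == "incomplete" && f >= target) {
        return(list(ok = TRUE, haplotypes = haps, generations = gen,
                    trajectory = traj))
      }
    }
  }
  if (mode %in% c("hard", "incomplete")) {
    return(list(ok = FALSE))  # never completed within the cap
  }
  list(ok = TRUE, haplotypes = haps, generations = gen, trajectory = traj)
}
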