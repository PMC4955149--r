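test_that("polymorphic-in-both filter applies the exact rule", {
  tbl <- tibble::tibble(
    snp_id = paste0("s", 1:5),
    freq1 = c(0.5, 1.0, 0.2, 0.0, 0.7),
    freq2 = c(0.4, 0.5, 1.0, 0.3, 0.6)
  )
  kept <- polymorphic_filter(tbl)
  expect_equal(kept$snp_id, c("s1", "s5"))  # s2 fixed in pop1, s3 in pop2, s4 lost in pop1

  all_poly <- tibble::tibble(snp_id = "a", freq1 = 0.5, freq2 = 0.5)
  expect_equal(polymorphic_filter(all_poly), all_poly)

  none <- tibble::tibble(snp_id = "a", freq1 = 1, freq2 = 0.5)
  expect_error(polymorphic_filter(none), "nothing to scan")
})

test_that("drift coefficient matches hand arithmetic and its floor", {
  two <- tibble::tibble(freq1 = c(0.6, 0.4), freq2 = c(0.5, 0.5))
  expect_equal(estimate_drift(two), (0.01 / 0.25 + 0.01 / 0.25) / 2)
  expect_equal(estimate_drift(two), 0.04)

  same <- tibble::tibble(freq1 = c(0.3, 0.8), freq2 = c(0.3, 0.8))
  expect_equal(estimate_drift(same), 1e-4)  # floored at zero differentiation
})

test_that("drift estimate approaches its Balding-Nichols expectation", {
  # with p2 ~ BN(p_anc, F) and p1 ~ BN(p_anc, F), E[(p1-p2)^2 | p2] has no
  # closed form over the p2 denominator, so check against a brute-force
  # Monte-Carlo evaluation of the same expectation at matched settings
  F <- 0.05
  cfg <- sim_config(n_snps = 20000, divergence_F = c(F, F), rng_seed = 31)
  fr <- simulate_divergence_freqs(cfg)
  est <- estimate_drift(tibble::tibble(freq1 = fr$p1, freq2 = fr$p2))

  set.seed(99)
  pa <- runif(2e5, 0.05, 0.95)
  draw <- function(p) rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  q1 <- draw(pa); q2 <- draw(pa)
  oracle <- mean((q1 - q2)^2 / (q2 * (1 - q2)))
  expect_lt(abs(est - oracle) / oracle, 0.1)
})

test_that("sweep mixture density integrates to one and matches quadrature", {
  grid <- expand.grid(p2 = c(0.2, 0.5, 0.8), omega = c(0.02, 0.1),
                      c_esc = c(0.25, 0.6, 1))
  for (i in seq_len(nrow(grid))) {
    p2 <- grid$p2[i]; om <- grid$omega[i]; ce <- grid$c_esc[i]
    total <- stats::integrate(function(x) sweep_mixture_density(x, p2, om, ce),
                              0, 1, rel.tol = 1e-9, subdivisions = 400)$value
    expect_lt(abs(total - 1), 1e-6)
    for (p1 in c(0.15, 0.5, 0.9)) {
      expect_equal(sweep_mixture_density(p1, p2, om, ce),
                   mixture_density_oracle(p1, p2, om, ce), tolerance = 1e-8)
    }
  }
})

test_that("the oracle-pinned log-density value is reproduced", {
  # frozen from the quadrature oracle: p1 = 0.9, p2 = 0.5, omega = 0.05,
  # c = 0.5 (computed in helper-fixtures.R independently of pnorm)
  oracle_val <- log(mixture_density_oracle(0.9, 0.5, 0.05, 0.5))
  got <- window_composite_loglik(p1 = 0.9, p2 = 0.5, r = log(2) * 0.01,
                                 omega = 0.05, q = 0.01)
  expect_equal(as.numeric(got), oracle_val, tolerance = 1e-8)
  # r chosen so c = 1 - exp(-r/q) = 0.5 exactly
})

test_that("q = 0 collapses the window likelihood to the neutral model exactly", {
  set.seed(7)
  p1 <- runif(30, 0.1, 0.9); p2 <- runif(30, 0.1, 0.9)
  r <- runif(30, 0, 0.01); w <- runif(30, 0.2, 1)
  neutral <- sum(w * log(sweep_mixture_density(p1, p2, 0.08, rep(1, 30))))
  expect_equal(as.numeric(window_composite_loglik(p1, p2, r, 0.08, 0, w)),
               neutral)
})

xp_fixture <- function(seed = 3, sweep = FALSE) {
  cfg <- sim_config(n_diploids = 200, n_sample = 40, n_snps = 300,
                    chromosome_length = 3e5,
                    sweep_site = if (sweep) 150 else NA, s = if (sweep) 0.15 else 0,
                    sweep_mode = "hard", n_generations = 25, rng_seed = seed)
  sim <- simulate_sweep_panel(cfg)
  list(sim = sim,
       freqs = population_freq_table(sim$panel, "pop1", "pop2"),
       ref = panel_population(sim$panel, "pop2"))
}

test_that("scan scores are non-negative, normalized, and zero when Q = {0}", {
  fx <- xp_fixture()
  null_scan <- xpclr_scan(fx$freqs, fx$ref, spacing = 1000, q_grid = 0)
  expect_true(all(null_scan$grid$score[!is.na(null_scan$grid$score)] == 0))

  scan <- xpclr_scan(fx$freqs, fx$ref, spacing = 1000)
  sc <- scan$grid$score
  expect_true(all(sc[!is.na(sc)] >= 0))
  z <- scan$scores$std_score
  expect_lt(abs(mean(z, na.rm = TRUE)), 1e-9)
  expect_lt(abs(var(z[!is.na(z)]) - 1), 1e-9)
  expect_true(all(scan$scores$snp_id %in% fx$freqs$snp_id))
})

test_that("scan is deterministic and invariant to input row order", {
  fx <- xp_fixture(seed = 5)
  a <- xpclr_scan(fx$freqs, fx$ref, spacing = 2000)
  b <- xpclr_scan(fx$freqs[sample(nrow(fx$freqs)), ], fx$ref, spacing = 2000)
  expect_equal(a$grid, b$grid)
  expect_equal(dplyr::arrange(a$scores, snp_id),
               dplyr::arrange(b$scores, snp_id))
})

test_that("mean sweep-site score increases with the selection coefficient", {
  # single-origin sweeps stopped at the same frequency (0.8): a larger s
  # gets there in fewer generations, so less recombination erodes the
  # hitchhiked differentiation and the site score grows with s; the 6 cM
  # map keeps the footprint of the fastest sweep inside the chromosome
  site_score <- function(s, seed) {
    cfg <- sim_config(n_diploids = 500, n_sample = 40, n_snps = 750,
                      chromosome_length = 1e6, recomb_rate = 6,
                      sweep_site = 375, s = s,
                      sweep_mode = "incomplete", sweep_target = 0.8,
                      sweep_start_freq = 0.001, n_generations = 50,
                      rng_seed = seed)
    sim <- simulate_sweep_panel(cfg)
    scan <- xpclr_scan(population_freq_table(sim$panel, "pop1", "pop2"),
                       panel_population(sim$panel, "pop2"), spacing = 1000)
    g <- scan$grid
    site_pos <- sim$panel$snps$pos[375]
    mean(g$score[abs(g$grid_pos - site_pos) <= 20000], na.rm = TRUE)
  }
  seeds <- 1:4
  s_levels <- c(0, 0.05, 0.1)
  means <- vapply(s_levels, function(s) {
    mean(vapply(seeds, function(sd) site_score(s, sd), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))  # monotone in s across replicate means
})
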