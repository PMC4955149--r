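uniform_gene_table <- function(scores, n_snps = 5L) {
  tibble::tibble(gene_id = names(scores), score = unname(scores),
                 n_snps = n_snps)
}

test_that("gene scores take the max |SNP score| and count SNPs per gene", {
  snp_scores <- tibble::tibble(snp_id = c("a", "b", "c", "d"),
                               score = c(1.5, -3, 0.5, NA))
  asn <- tibble::tibble(snp_id = c("a", "b", "b", "c", "d"),
                        gene_id = c("g1", "g1", "g2", "g2", "g3"))
  gs <- gene_scores(snp_scores, asn)
  expect_equal(gs$score[gs$gene_id == "g1"], 3)   # |-3|
  expect_equal(gs$score[gs$gene_id == "g2"], 3)
  expect_equal(gs$n_snps[gs$gene_id == "g1"], 2L)
  expect_false("g3" %in% gs$gene_id)              # undefined score dropped
})

test_that("sum engine p-values match exhaustive enumeration over C(10,3) subsets", {
  scores <- setNames(c(10, 9, 8, 1, 1, 1, 1, 1, 1, 1), paste0("g", 1:10))
  tbl <- uniform_gene_table(scores)
  sets <- list(top = c("g1", "g2", "g3"), mid = c("g1", "g4", "g5"))

  # oracle: enumerate all 120 equally likely null subsets
  combos <- combn(names(scores), 3)
  sums <- apply(combos, 2, function(g) sum(scores[g]))
  p_or <- function(obs) mean(sums >= obs - 1e-12)

  B <- 20000
  res <- sumscore_gsea(tbl, sets, n_bins = 3, B = B, seed = 42)
  for (nm in names(sets)) {
    obs <- sum(scores[sets[[nm]]])
    p_hat <- res$p[res$set == nm]
    se <- sqrt(p_or(obs) * (1 - p_or(obs)) / B)
    expect_lt(abs(p_hat - p_or(obs)), 3 * se + 2 / B)
  }
  expect_equal(res$statistic[res$set == "top"], 27)
})

test_that("degenerate equal scores give p = 1 and p is never zero", {
  tbl <- uniform_gene_table(setNames(rep(2, 12), paste0("g", 1:12)))
  res <- sumscore_gsea(tbl, list(s1 = paste0("g", 1:4)), B = 200, seed = 1)
  expect_equal(res$p, 1)

  skewed <- uniform_gene_table(setNames(c(100, rep(0, 11)), paste0("g", 1:12)))
  res2 <- sumscore_gsea(skewed, list(s1 = "g1"), B = 200, seed = 1)
  expect_gte(res2$p, 1 / 201)
  expect_identical(res2$p,
                   sumscore_gsea(skewed, list(s1 = "g1"), B = 200, seed = 1)$p)
})

test_that("bias-matched nulls sample from the right SNP-count bins", {
  # 8 long genes (many SNPs, two carrying all the signal) and 8 short
  # ones: with 2 rank bins the null set for {top two long genes} draws
  # only long genes, so p -> 1/C(8,2); unmatched sampling over all 16
  # genes would give ~1/C(16,2) instead
  tbl <- tibble::tibble(
    gene_id = paste0("g", 1:16),
    score = c(5, 4, rep(0.1, 6), rep(0.2, 8)),
    n_snps = c(50:57, rep(1L, 8))
  )
  B <- 4000
  res <- sumscore_gsea(tbl, list(big = c("g1", "g2")), n_bins = 2,
                       B = B, seed = 3)
  p_matched <- 1 / choose(8, 2)
  expect_lt(abs(unname(res$p) - p_matched),
            3 * sqrt(p_matched * (1 - p_matched) / B) + 2 / B)
})

test_that("overlap pruning drops duplicates, keeps disjoint sets unchanged", {
  set.seed(5)
  scores <- setNames(c(rnorm(20)^2, 8, 9, 10), paste0("g", 1:23))
  tbl <- uniform_gene_table(scores)
  sets <- list(
    hot = paste0("g", 12:23),            # contains the three big scores
    copy = paste0("g", 12:23),
    cold = paste0("g", 1:11)
  )
  res <- sumscore_gsea(tbl, sets, n_bins = 1, B = 500, seed = 9)
  pruned <- prune_overlapping_genes(res, sets, tbl, min_size = 10)
  st <- setNames(pruned$status, pruned$set)
  expect_equal(unname(st[c("hot", "copy")][order(names(st[c("hot", "copy")]))]),
               sort(c("tested", "dropped_overlap")))
  expect_equal(unname(st["cold"]), "tested")
  # disjoint set keeps its original p-value
  expect_equal(pruned$p[pruned$set == "cold"], res$p[res$set == "cold"])

  disjoint <- list(a = paste0("g", 1:10), b = paste0("g", 13:22))
  res_d <- sumscore_gsea(tbl, disjoint, n_bins = 1, B = 500, seed = 9)
  pruned_d <- prune_overlapping_genes(res_d, disjoint, tbl, min_size = 10)
  expect_equal(sort(pruned_d$p), sort(res_d$p))
  expect_true(all(pruned_d$status == "tested"))
})

test_that("pruning strips the signal genes from a superset and its p rises", {
  # B (10 genes, all the signal) inside A (20 genes); B ranks better, so A
  # is re-tested without B's genes and must look worse
  scores <- setNames(c(rep(6, 10), rep(0.1, 10), abs(rnorm(30, 0, 0.1))),
                     paste0("g", 1:50))
  tbl <- uniform_gene_table(scores)
  sets <- list(inner = paste0("g", 1:10), outer = paste0("g", 1:20))
  res <- sumscore_gsea(tbl, sets, n_bins = 1, B = 1000, seed = 2)
  # both sets may saturate at the minimum p; the tie-break (smaller set
  # first) then still ranks `inner` ahead of `outer`
  expect_lte(res$p[res$set == "inner"], res$p[res$set == "outer"])
  pruned <- prune_overlapping_genes(res, sets, tbl, min_size = 10)
  expect_equal(pruned$status[pruned$set == "outer"], "retested_pruned")
  expect_gt(pruned$p[pruned$set == "outer"], res$p[res$set == "outer"])
  expect_setequal(pruned$pruned_genes[pruned$set == "outer"][[1]],
                  paste0("g", 1:10))
})

test_that("candidate engine saturates at p = 1 and converges to the hypergeometric tail", {
  # one SNP per gene, equal lengths: permutation null is exactly
  # hypergeometric(N = 100 genes, K = 20 in set, n = 10 candidates)
  N <- 100; K <- 20; n_cand <- 10
  snp_scores <- tibble::tibble(snp_id = sprintf("s%03d", 1:N),
                               score = c(rep(5, n_cand), rep(0.1, N - n_cand)))
  asn <- tibble::tibble(snp_id = snp_scores$snp_id,
                        gene_id = sprintf("g%03d", 1:N))
  set_members <- sprintf("g%03d", c(1:6, 30:43))  # 6 candidate genes inside
  obs <- 6
  B <- 100000
  res <- candidate_gsea(snp_scores, asn, list(S = set_members),
                        percentile = 10, B = B, seed = 17)
  expect_equal(res$statistic, obs)
  p_true <- phyper(obs - 1, K, N - K, n_cand, lower.tail = FALSE)
  se <- sqrt(p_true * (1 - p_true) / B)
  expect_lt(abs(res$p - p_true), 3 * se)

  sat <- candidate_gsea(dplyr::mutate(snp_scores, score = 1), asn,
                        list(S = set_members), percentile = 40, B = 300,
                        seed = 1)
  expect_equal(sat$p, 1)  # ties at the cutoff include every SNP

  expect_error(candidate_gsea(snp_scores, asn, list(S = set_members),
                              percentile = 60), "percentile")
})

test_that("candidate engine counts genes once in gene mode, SNPs in snp mode", {
  snp_scores <- tibble::tibble(snp_id = paste0("s", 1:10),
                               score = c(9, 8, 7, rep(0.1, 7)))
  asn <- tibble::tibble(snp_id = paste0("s", c(1, 2, 3, 4:10)),
                        gene_id = c("g1", "g1", "g2", paste0("g", 3:9)))
  g <- candidate_gsea(snp_scores, asn, list(S = c("g1", "g2")),
                      percentile = 30, B = 200, seed = 4)
  expect_equal(g$statistic, 2)  # g1 hit twice counts once
  s <- candidate_gsea(snp_scores, asn, list(S = c("g1", "g2")),
                      percentile = 30, B = 200, seed = 4, mode = "snp")
  expect_equal(s$statistic, 3)
})

test_that("Benjamini-Hochberg q-values match hand computation", {
  expect_equal(compute_qvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))  # p_(i) * 4 / i = 0.04 for every rank
  expect_equal(compute_qvalues(0.5), 0.5)
  expect_equal(compute_qvalues(rep(1, 5)), rep(1, 5))
  expect_error(compute_qvalues(numeric(0)), "empty")
  # step-up monotonicity on an uneven ladder
  p <- c(0.001, 0.04, 0.041, 0.9)
  q <- compute_qvalues(p)
  expect_true(all(diff(q[order(p)]) >= 0))
})
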