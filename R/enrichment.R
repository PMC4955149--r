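#' Gene-level selection scores from a SNP score track
#'
#' A gene's selection score is the maximum absolute normalized SNP score
#' over the SNPs assigned to it (two-sided: both extremes of a
#' standardized scan indicate sweeps). The SNP count per gene is carried
#' along because the enrichment null matches on it to neutralize
#' gene-length bias.
#'
#' @param snp_scores Data frame with `snp_id` and `score` (a normalized
#'   scan score; `std_ihs` / `std_score` columns are picked up
#'   automatically from scan results via [tidy()]).
#' @param assignments SNP-to-gene table (`snp_id`, `gene_id`), e.g. from
#'   [assign_snps_to_genes()].
#' @return Tibble with `gene_id`, `score`, `n_snps` for scored genes.
#' @export
gene_scores <- function(snp_scores, assignments) {
  s <- as_tibble(snp_scores)
  if (!"score" %in% names(s)) {
    cand <- intersect(c("std_score", "std_ihs"), names(s))
    if (!length(cand)) abort("snp_scores needs a 'score' column")
    s$score <- s[[cand[1]]]
  }
  inner_join(as_tibble(assignments), s[, c("snp_id", "score")], by = "snp_id") |>
    filter(!is.na(.data$score)) |>
    group_by(.data$gene_id) |>
    summarise(score = max(abs(.data$score)), n_snps = n(), .groups = "drop")
}

# equal-occupancy bins of genes by SNP-count rank (rank bins never collapse
# under the long-tailed SNP-count distributions quantile breaks choke on);
# bins left too small are merged with their left neighbour
snp_count_bins <- function(n_snps, n_bins, min_per_bin = 2L) {
  r <- rank(n_snps, ties.method = "first")
  bin <- as.integer(ceiling(n_bins * r / length(n_snps)))
  # genes with equal SNP counts are interchangeable for the null and must
  # share a bin; pull every tie group into its lowest provisional bin
  bin <- stats::ave(bin, n_snps, FUN = min)
  repeat {
    sizes <- table(bin)
    bad <- as.integer(names(sizes))[sizes < min_per_bin]
    if (!length(bad)) break
    b <- bad[1]
    others <- setdiff(unique(bin), b)
    if (!length(others)) break
    left <- others[others < b]
    bin[bin == b] <- if (length(left)) max(left) else min(others)
  }
  match(bin, sort(unique(bin)))
}

#' Sum-of-gene-scores enrichment with bias-matched permutation nulls
#'
#' The observed statistic of a set is the sum of its gene scores. The
#' null distribution is built from `B` random sets matched for
#' gene-length bias: genes are binned by SNP count into `n_bins` quantile
#' bins, and each null set replaces every member gene by a random,
#' not-yet-used gene from the same bin. The permutation p-value is
#' `(1 + #\{S_null >= S_obs\}) / (1 + B)`, so it is never 0.
#'
#' @param gene_score_tbl Output of [gene_scores()] (columns `gene_id`,
#'   `score`, `n_snps`), covering every set member.
#' @param collection Named list of gene-id vectors, or a
#'   `geneset_collection` from [prepare_genesets()].
#' @param n_bins Number of SNP-count bins (default 10).
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return A `gsea_result` tibble: `set`, `n_genes`, `statistic`, `p`,
#'   `q`, `status`; attributes `engine`, `B`, `seed`.
#' @export
sumscore_gsea <- function(gene_score_tbl, collection, n_bins = 10,
                          B = 10000, seed = 1L) {
  if (B < 100) abort("B must be >= 100")
  sets <- if (inherits(collection, "geneset_collection")) collection$sets else collection
  g <- as_tibble(gene_score_tbl)
  missing <- setdiff(unique(unlist(sets)), g$gene_id)
  if (length(missing)) {
    abort(paste("set members without a gene score:",
                paste(head(missing, 5), collapse = ", ")))
  }
  bin <- snp_count_bins(g$n_snps, n_bins)
  score <- setNames(g$score, g$gene_id)
  bin_of <- setNames(bin, g$gene_id)
  by_bin <- split(seq_len(nrow(g)), bin)

  set.seed(seed)
  res <- purrr::imap(sets, function(members, nm) {
    idx <- match(members, g$gene_id)
    s_obs <- sum(score[idx])
    need <- table(bin_of[members])  # genes required per bin
    exceed <- 0L
    for (b in seq_len(B)) {
      s_null <- 0
      for (bn in names(need)) {
        pool <- by_bin[[bn]]
        k <- need[[bn]]
        take <- if (length(pool) == 1L) pool else sample(pool, k)
        s_null <- s_null + sum(g$score[take])
      }
      if (s_null >= s_obs - 1e-12) exceed <- exceed + 1L
    }
    tibble(set = nm, n_genes = length(members), statistic = s_obs,
           p = (1 + exceed) / (1 + B))
  }) |> purrr::list_rbind()
  res$q <- compute_qvalues(res$p)
  res$status <- "tested"
  structure(res, engine = "sumscore", B = B, seed = seed, n_bins = n_bins,
            class = c("gsea_result", class(res)))
}

#' Overlap correction: prune genes claimed by better-ranked sets
#'
#' Sets are ranked by p-value (ties: smaller set first, then name).
#' Walking down the ranking, genes already claimed by a better-ranked set
#' are removed from the current set; pruned sets that fall below
#' `min_size` genes are dropped (`status = "dropped_overlap"`), and
#' surviving pruned sets are re-tested with the sum engine in a single
#' pass. This prevents one selected region shared by several sets from
#' making them all significant.
#'
#' @param results A `gsea_result` from [sumscore_gsea()].
#' @param collection The collection the results were computed on.
#' @param gene_score_tbl The gene score table used for testing.
#' @param min_size Size floor applied after pruning (default 10).
#' @param n_bins,B,seed Re-testing parameters (defaults: those of
#'   `results`).
#' @return A `gsea_result` with re-tested p/q values, a `pruned_genes`
#'   list-column and updated `status`.
#' @export
prune_overlapping_genes <- function(results, collection, gene_score_tbl,
                                    min_size = 10, n_bins = NULL,
                                    B = NULL, seed = NULL) {
  sets <- if (inherits(collection, "geneset_collection")) collection$sets else collection
  B <- B %||% attr(results, "B")
  n_bins <- n_bins %||% attr(results, "n_bins")
  seed <- seed %||% (attr(results, "seed") + 1L)

  ord <- order(results$p, results$n_genes, results$set)
  claimed <- character(0)
  kept <- list()
  dropped <- character(0)
  pruned_genes <- list()
  for (i in ord) {
    nm <- results$set[i]
    members <- sets[[nm]]
    lost <- intersect(members, claimed)
    remaining <- setdiff(members, claimed)
    pruned_genes[[nm]] <- lost
    if (length(remaining) < min_size) {
      dropped <- c(dropped, nm)
    } else {
      kept[[nm]] <- remaining
      claimed <- union(claimed, remaining)
    }
  }

  was_pruned <- names(kept)[lengths(pruned_genes[names(kept)]) > 0]
  unchanged <- filter(as_tibble(results), .data$set %in% setdiff(names(kept), was_pruned)) |>
    select("set", "n_genes", "statistic", "p") |>
    mutate(status = "tested")
  retested <- if (length(was_pruned)) {
    sumscore_gsea(gene_score_tbl, kept[was_pruned], n_bins = n_bins, B = B,
                  seed = seed) |>
      as_tibble() |>
      select("set", "n_genes", "statistic", "p") |>
      mutate(status = "retested_pruned")
  } else NULL
  out <- bind_rows(unchanged, retested)
  out$q <- compute_qvalues(out$p)
  out <- bind_rows(
    out,
    tibble(set = dropped,
           n_genes = purrr::map_int(dropped, \(nm) length(sets[[nm]])),
           statistic = NA_real_, p = NA_real_, q = NA_real_,
           status = "dropped_overlap")
  )
  out$pruned_genes <- pruned_genes[out$set]
  structure(out, engine = "sumscore_pruned", B = B, seed = seed,
            n_bins = n_bins, class = c("gsea_result", class(out)))
}

#' Candidate-SNP enrichment with genome-wide SNP permutation
#'
#' Candidate SNPs are those whose absolute score lies in the top
#' `percentile` percent of all scored SNPs (ties at the cutoff are all
#' included). A set's observed statistic is the number of member genes
#' containing at least one candidate SNP. Each of `B` permutations
#' redraws the same number of SNPs uniformly without replacement from all
#' scored SNPs and recounts; because genes are hit in proportion to their
#' SNP content, this null automatically accounts for gene length and
#' overlap. `mode = "snp"` counts candidate SNPs inside member genes
#' instead of genes hit.
#'
#' @param snp_scores Data frame with `snp_id` and `score` (absolute values
#'   are taken).
#' @param assignments SNP-to-gene table (`snp_id`, `gene_id`).
#' @param collection Named list of gene sets or a `geneset_collection`.
#' @param percentile Candidate cutoff percentile in (0, 50); default 1.
#' @param B Number of permutations (default 100000).
#' @param seed Integer seed.
#' @param mode `"gene"` (default) or `"snp"` counting.
#' @return A `gsea_result` tibble (`set`, `n_genes`, `statistic`, `p`,
#'   `q`, `status`) with attributes `engine`, `B`, `seed`, `n_candidates`.
#' @export
candidate_gsea <- function(snp_scores, assignments, collection,
                           percentile = 1, B = 100000, seed = 1L,
                           mode = c("gene", "snp")) {
  mode <- match.arg(mode)
  if (percentile <= 0 || percentile >= 50) abort("percentile must be in (0, 50)")
  sets <- if (inherits(collection, "geneset_collection")) collection$sets else collection
  s <- as_tibble(snp_scores)
  if (!"score" %in% names(s)) {
    cand <- intersect(c("std_score", "std_ihs"), names(s))
    if (!length(cand)) abort("snp_scores needs a 'score' column")
    s$score <- s[[cand[1]]]
  }
  s <- filter(s, !is.na(.data$score))
  n_snp <- nrow(s)
  a <- abs(s$score)
  k <- max(1L, ceiling(percentile / 100 * n_snp))
  cutoff <- sort(a, decreasing = TRUE)[k]
  is_cand <- a >= cutoff  # ties at the cutoff all included
  n_cand <- sum(is_cand)
  if (!n_cand) abort("no candidate SNPs at this percentile")

  asn <- as_tibble(assignments)
  gene_ids <- sort(unique(asn$gene_id))
  gene_of_snp <- split(match(asn$gene_id, gene_ids),
                       factor(asn$snp_id, levels = s$snp_id))
  member <- matrix(FALSE, length(gene_ids), length(sets),
                   dimnames = list(gene_ids, names(sets)))
  for (nm in names(sets)) {
    member[intersect(sets[[nm]], gene_ids), nm] <- TRUE
  }

  count_stat <- function(snp_idx) {
    hit <- unlist(gene_of_snp[snp_idx], use.names = FALSE)
    if (mode == "gene") {
      hit <- unique(hit)
      colSums(member[hit, , drop = FALSE])
    } else {
      colSums(member[hit, , drop = FALSE])  # with multiplicity
    }
  }
  obs <- count_stat(which(is_cand))

  set.seed(seed)
  exceed <- integer(length(sets))
  for (b in seq_len(B)) {
    cnt <- count_stat(sample.int(n_snp, n_cand))
    exceed <- exceed + (cnt >= obs)
  }
  res <- tibble(
    set = names(sets),
    n_genes = unname(lengths(sets)),
    statistic = unname(as.numeric(obs)),
    p = unname((1 + exceed) / (1 + B))
  )
  res$q <- compute_qvalues(res$p)
  res$status <- "tested"
  structure(res, engine = "candidate", B = B, seed = seed,
            n_candidates = n_cand, percentile = percentile, mode = mode,
            class = c("gsea_result", class(res)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with the usual monotonicity
#' enforcement; sets are called significant at `q <= 0.09` downstream.
#'
#' @param p Vector of p-values in (0, 1].
#' @return q-values of the same length.
#' @export
compute_qvalues <- function(p) {
  if (!length(p)) abort("empty p-value vector")
  p.adjust(p, method = "BH")
}
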