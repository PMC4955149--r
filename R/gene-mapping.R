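#' Consensus filter of SNP positions from two mapping sources
#'
#' Keeps only SNPs that two independent position sources (e.g. two
#' assembly remappings) place at the identical chromosome and position;
#' everything else is discarded and the discard count reported.
#'
#' @param mapping_a,mapping_b Data frames with `snp_id`, `chrom`, `pos`.
#' @return Tibble of retained `snp_id`, `chrom`, `pos`.
#' @export
consensus_position_filter <- function(mapping_a, mapping_b) {
  a <- as_tibble(mapping_a)[, c("snp_id", "chrom", "pos")]
  b <- as_tibble(mapping_b)[, c("snp_id", "chrom", "pos")]
  out <- inner_join(a, b, by = c("snp_id", "chrom", "pos"))
  n_drop <- nrow(a) - nrow(out)
  if (!nrow(out)) abort("no SNP has a consensus position across the two mappings")
  if (n_drop > 0) {
    inform(sprintf("consensus filter discarded %d of %d SNPs", n_drop, nrow(a)))
  }
  out
}

#' Collapse isoforms to gene union intervals
#'
#' For genes with several isoforms the gene interval is the utmost start
#' and utmost end over all of them (the longest-isoform rule).
#'
#' @param gene_models Tibble of isoform intervals: `gene_id`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @return One row per gene: `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_union_intervals <- function(gene_models) {
  as_tibble(gene_models) |>
    group_by(.data$gene_id, .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
}

#' Assign SNPs to genes by union-interval containment
#'
#' A SNP belongs to a gene iff `union_start <= pos <= union_end` on the
#' same chromosome (1-based inclusive on both ends); a SNP inside
#' overlapping genes is assigned to all of them. Flanking sequence can be
#' added around each gene with `flank_bp` (default 0).
#'
#' @param snp_positions Tibble with `snp_id`, `chrom`, `pos` (typically
#'   the output of [consensus_position_filter()]).
#' @param gene_models Isoform intervals (see [gene_union_intervals()]).
#' @param flank_bp Symmetric flank added to each gene union interval.
#' @return A list with `assignments` (tibble `snp_id`, `gene_id`),
#'   `gene_snps` (tibble `gene_id`, `n_snps`, `snp_ids` list-column,
#'   including zero-SNP genes flagged by `scored = FALSE`).
#' @export
assign_snps_to_genes <- function(snp_positions, gene_models, flank_bp = 0) {
  snp_positions <- as_tibble(snp_positions)
  genes <- gene_union_intervals(gene_models) |>
    mutate(start = .data$start - flank_bp, end = .data$end + flank_bp)

  pieces <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    s <- snp_positions[snp_positions$chrom == ch, ]
    if (!nrow(s) || !nrow(g)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(s$pos, s$pos),
      IRanges::IRanges(g$start, g$end)
    )
    pieces[[ch]] <- tibble(
      snp_id = s$snp_id[S4Vectors::queryHits(hits)],
      gene_id = g$gene_id[S4Vectors::subjectHits(hits)]
    )
  }
  assignments <- if (length(pieces)) purrr::list_rbind(pieces) else
    tibble(snp_id = character(0), gene_id = character(0))

  gene_snps <- assignments |>
    group_by(.data$gene_id) |>
    summarise(n_snps = n(), snp_ids = list(.data$snp_id), .groups = "drop")
  gene_snps <- genes |>
    select("gene_id") |>
    left_join(gene_snps, by = "gene_id") |>
    mutate(
      n_snps = coalesce(.data$n_snps, 0L),
      snp_ids = purrr::map(.data$snp_ids, \(x) x %||% character(0)),
      scored = .data$n_snps > 0L
    )
  list(assignments = assignments, gene_snps = gene_snps)
}
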