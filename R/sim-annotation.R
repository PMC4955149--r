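#' Generate gene models, gene sets and a disease list for a panel
#'
#' Produces the annotation side of a synthetic dataset: genes tiling the
#' simulated chromosome with 1-3 isoforms each, overlapping gene sets of
#' configurable size and pairwise Jaccard similarity, one "planted" set
#' containing the genes around the sweep site, and a disease-gene list that
#' overlaps the high-scoring region at a configurable rate.
#'
#' When `set_jaccard` is given, sets are emitted in consecutive pairs
#' sharing `round(2 * size * J / (1 + J))` genes, the integer whose Jaccard
#' is closest to the request; `set_jaccard = 1` gives identical pairs.
#'
#' @param config A [sim_config()] (supplies the seed).
#' @param sim A `sweep_sim` from [simulate_sweep_panel()] (or a bare
#'   [haplotype_panel()] for neutral data).
#' @param gene_length_range Gene union length range in bp.
#' @param gap_range Intergenic gap range in bp.
#' @param n_sets Number of gene sets (in addition to the planted set).
#' @param set_size Genes per set.
#' @param set_jaccard Optional pairwise Jaccard similarity for consecutive
#'   set pairs; `NULL` draws independent random sets.
#' @param planted_flank Bp around the sweep site whose genes seed the
#'   planted set (padded with random genes up to `set_size`). The default
#'   (100 kb) spans the region where a completed sweep still leaves
#'   polymorphic, scorable SNPs; genes inside the fixed core of a sweep
#'   receive no scores and cannot carry a set.
#' @param disease_size Number of disease-list genes.
#' @param disease_overlap Fraction of the disease list drawn from the
#'   planted set's genes (the rest are random).
#' @return An `annotation_bundle`: list with `gene_models` (tibble of
#'   isoform intervals: `gene_id`, `chrom`, `start`, `end`), `gene_sets`
#'   (named list of gene-id vectors; includes `"planted"` when the panel
#'   has a sweep), `disease_genes` (character), `planted_set` (name or NA).
#' @export
generate_annotation_bundle <- function(config, sim,
                                       gene_length_range = c(3e3, 12e3),
                                       gap_range = c(0, 3e3),
                                       n_sets = 20, set_size = 15,
                                       set_jaccard = NULL,
                                       planted_flank = 1e5,
                                       disease_size = 15,
                                       disease_overlap = 0.5) {
  panel <- if (inherits(sim, "sweep_sim")) sim$panel else sim
  sweep <- if (inherits(sim, "sweep_sim")) sim$sweep else NULL
  set.seed(derive_seed(config$rng_seed, "annotation"))

  L <- config$chromosome_length
  chroms <- unique(panel$snps$chrom)
  starts <- ends <- integer(0)
  gene_chrom <- character(0)
  for (ch in chroms) {
    cursor <- 1 + round(runif(1, gap_range[1], gap_range[2]))
    while (cursor < L) {
      len <- round(runif(1, gene_length_range[1], gene_length_range[2]))
      if (cursor + len - 1 > L) break
      starts <- c(starts, cursor)
      ends <- c(ends, cursor + len - 1)
      gene_chrom <- c(gene_chrom, ch)
      cursor <- cursor + len + round(runif(1, gap_range[1], gap_range[2]))
    }
  }
  n_genes <- length(starts)
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))

  # 1-3 isoforms: the first spans the union so the utmost-start/end rule
  # recovers exactly (start, end); extras are random subintervals
  gene_models <- purrr::map(seq_len(n_genes), function(i) {
    n_iso <- sample(1:3, 1)
    iso_start <- starts[i]
    iso_end <- ends[i]
    if (n_iso > 1) {
      s2 <- round(runif(n_iso - 1, starts[i], (starts[i] + ends[i]) / 2))
      e2 <- round(runif(n_iso - 1, (starts[i] + ends[i]) / 2, ends[i]))
      iso_start <- c(iso_start, s2)
      iso_end <- c(iso_end, e2)
    }
    tibble(gene_id = gene_ids[i], chrom = gene_chrom[i],
           start = as.integer(iso_start), end = as.integer(iso_end))
  }) |> purrr::list_rbind()

  if (set_size > n_genes) {
    abort(sprintf("requested set size %d exceeds gene count %d",
                  set_size, n_genes))
  }

  gene_sets <- list()
  if (!is.null(set_jaccard)) {
    shared <- round(2 * set_size * set_jaccard / (1 + set_jaccard))
    for (p in seq_len(ceiling(n_sets / 2))) {
      core <- sample(gene_ids, 2 * set_size - shared)
      a <- core[seq_len(set_size)]
      b <- c(a[seq_len(shared)],
             core[set_size + seq_len(set_size - shared)])
      gene_sets[[sprintf("set%02da", p)]] <- a
      gene_sets[[sprintf("set%02db", p)]] <- b
    }
    gene_sets <- gene_sets[seq_len(n_sets)]
  } else {
    for (i in seq_len(n_sets)) {
      gene_sets[[sprintf("set%02d", i)]] <- sample(gene_ids, set_size)
    }
  }

  planted_set <- NA_character_
  planted_genes <- character(0)
  if (!is.null(sweep) && !is.na(sweep$sweep_site)) {
    sp <- sweep$sweep_pos
    on_chrom <- gene_chrom == sweep$sweep_chrom
    near <- gene_ids[on_chrom & ends >= sp - planted_flank &
                       starts <= sp + planted_flank]
    planted_genes <- near
    if (length(planted_genes) < set_size) {
      planted_genes <- c(planted_genes,
                         sample(setdiff(gene_ids, planted_genes),
                                set_size - length(planted_genes)))
    }
    gene_sets[["planted"]] <- planted_genes
    planted_set <- "planted"
  }

  n_from_planted <- min(length(planted_genes),
                        round(disease_overlap * disease_size))
  disease_genes <- unique(c(
    sample(planted_genes, n_from_planted),
    sample(setdiff(gene_ids, planted_genes), disease_size - n_from_planted)
  ))

  structure(
    list(gene_models = gene_models, gene_sets = gene_sets,
         disease_genes = disease_genes, planted_set = planted_set),
    class = "annotation_bundle"
  )
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf(
    "<annotation_bundle> %d genes (%d isoform records), %d gene sets, %d disease genes%s\n",
    length(unique(x$gene_models$gene_id)), nrow(x$gene_models),
    length(x$gene_sets), length(x$disease_genes),
    if (!is.na(x$planted_set)) sprintf(", planted set '%s'", x$planted_set) else ""
  ))
  invisible(x)
}
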