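#' Pipeline configuration
#'
#' Bundles every input path and stage parameter of the end-to-end
#' analysis. Defaults follow the published settings where settings exist:
#' 200 bp grid spacing, 50-SNP windows, MAF floor 0.05, minimum set size
#' 10, merge threshold 0.95, candidate percentile 1, q threshold 0.09.
#'
#' @param vcf,map,bed,gmt,disease_list Input file paths (phased VCF,
#'   genetic-map TSV, isoform BED, gene-set GMT, plain-text disease list).
#' @param positions_b Optional second SNP-position TSV (`snp_id`, `chrom`,
#'   `pos`) for the consensus-position filter; `NULL` skips it.
#' @param populations Named character vector or data frame mapping
#'   `sample_id` to population.
#' @param objective,reference Population labels for the cross-population
#'   scan.
#' @param out_dir Output directory.
#' @param scans Which scans to run: subset of `c("xpclr", "ihs")`.
#' @param spacing,window_snps,maf_min,ihs_bins,min_set_size,
#'   merge_threshold,candidate_percentile,q_threshold,sum_B,cand_B,
#'   gene_bins Stage parameters (see the stage functions).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, map, bed, gmt, disease_list,
                            populations, objective, reference,
                            out_dir, positions_b = NULL,
                            scans = c("xpclr", "ihs"),
                            spacing = 200, window_snps = 50,
                            maf_min = 0.05, ihs_bins = 20,
                            min_set_size = 10, merge_threshold = 0.95,
                            candidate_percentile = 1, q_threshold = 0.09,
                            sum_B = 10000, cand_B = 100000,
                            gene_bins = 10, seed = 1L) {
  scans <- match.arg(scans, several.ok = TRUE)
  cfg <- list(
    vcf = vcf, map = map, bed = bed, gmt = gmt,
    disease_list = disease_list, positions_b = positions_b,
    populations = populations, objective = objective,
    reference = reference, out_dir = out_dir, scans = scans,
    spacing = spacing, window_snps = window_snps, maf_min = maf_min,
    ihs_bins = ihs_bins, min_set_size = min_set_size,
    merge_threshold = merge_threshold,
    candidate_percentile = candidate_percentile,
    q_threshold = q_threshold, sum_B = sum_B, cand_B = cand_B,
    gene_bins = gene_bins, seed = as.integer(seed)
  )
  for (f in c("vcf", "map", "bed", "gmt", "disease_list")) {
    if (!file.exists(cfg[[f]])) abort(sprintf("input '%s' not found: %s", f, cfg[[f]]))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; `populations` may be a `sample: population`
#'   mapping.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.list(y$populations)) y$populations <- unlist(y$populations)
  do.call(pipeline_config, y)
}

#' Run the full polygenic-selection pipeline
#'
#' Executes, in order: input parsing, (optional) consensus-position
#' filtering, the configured selection scans, SNP-to-gene assignment,
#' gene-set preparation, both enrichment engines per scan (sum engine
#' with overlap pruning, candidate engine), q-value control and
#' disease-gene flagging. Every output table carries a provenance header
#' with the package version, the parameters and the seed; re-running the
#' same config on the same inputs is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle (list): `panel`, `scans` (named list of scan
#'   objects), `gene_map`, `collections`, `enrichment` (named list of
#'   `gsea_result`s), `disease` (named list of `disease_report`s) and
#'   `manifest` (tibble of input checksums and parameters), invisibly;
#'   the tables are also written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ver <- as.character(utils::packageVersion("sweepsets"))
  hdr <- function(extra = character(0)) c(
    sprintf("sweepsets %s", ver),
    sprintf("seed: %d", config$seed),
    sprintf("objective: %s  reference: %s", config$objective, config$reference),
    extra
  )

  inputs <- stage("read_inputs", {
    map <- read_genetic_map(config$map)
    panel <- read_haplotypes(config$vcf, config$populations, map = map)
    list(
      map = map, panel = panel,
      gene_models = read_bed_genes(config$bed),
      sets = read_gmt(config$gmt),
      disease = read_gene_list(config$disease_list)
    )
  })
  panel <- inputs$panel

  positions <- tibble(snp_id = panel$snps$snp_id, chrom = panel$snps$chrom,
                      pos = panel$snps$pos)
  if (!is.null(config$positions_b)) {
    positions <- stage("consensus_filter", {
      b <- readr::read_tsv(config$positions_b, show_col_types = FALSE)
      consensus_position_filter(positions, b)
    })
  }

  scans <- list()
  if ("xpclr" %in% config$scans) {
    scans$xpclr <- stage("scan_xpclr", {
      fr <- panel_frequencies(panel)
      freqs <- tibble(
        snp_id = panel$snps$snp_id,
        freq1 = fr$freq[fr$population == config$objective],
        freq2 = fr$freq[fr$population == config$reference]
      )
      xpclr_scan(freqs, panel_population(panel, config$reference),
                 spacing = config$spacing, window_snps = config$window_snps)
    })
  }
  if ("ihs" %in% config$scans) {
    scans$ihs <- stage("scan_ihs", {
      ihs_scan(panel_population(panel, config$objective),
               maf_min = config$maf_min, n_bins = config$ihs_bins)
    })
  }

  gene_map <- stage("gene_mapping", {
    assign_snps_to_genes(positions, inputs$gene_models)
  })

  enrichment <- list()
  collections <- list()
  disease <- list()
  for (sc in names(scans)) {
    snp_scores <- tidy(scans[[sc]]) |>
      filter(.data$snp_id %in% positions$snp_id)
    gsc <- stage(paste0("gene_scores_", sc), {
      gene_scores(snp_scores, gene_map$assignments)
    })
    coll <- stage(paste0("prep_sets_", sc), {
      prepare_genesets(inputs$sets, scored_genes = gsc$gene_id,
                       min_size = config$min_set_size,
                       merge_threshold = config$merge_threshold)
    })
    collections[[sc]] <- coll
    sum_res <- stage(paste0("gsea_sum_", sc), {
      sumscore_gsea(gsc, coll, n_bins = config$gene_bins, B = config$sum_B,
                    seed = derive_seed(config$seed, paste0("sum_", sc)))
    })
    sum_pruned <- stage(paste0("gsea_sum_prune_", sc), {
      prune_overlapping_genes(sum_res, coll, gsc,
                              min_size = config$min_set_size)
    })
    cand_res <- stage(paste0("gsea_cand_", sc), {
      candidate_gsea(snp_scores, gene_map$assignments, coll,
                     percentile = config$candidate_percentile,
                     B = config$cand_B,
                     seed = derive_seed(config$seed, paste0("cand_", sc)))
    })
    enrichment[[paste0(sc, "_sum")]] <- sum_pruned
    enrichment[[paste0(sc, "_candidate")]] <- cand_res
    disease[[sc]] <- stage(paste0("disease_", sc), {
      flag_disease_genes(gsc, inputs$disease)
    })

    write_tsv_with_header(tidy(scans[[sc]]),
                          file.path(config$out_dir, paste0("scores_", sc, ".tsv")),
                          hdr(sprintf("scan: %s", sc)))
    write_tsv_with_header(
      tidy(sum_pruned, q_threshold = config$q_threshold) |>
        select(-"pruned_genes"),
      file.path(config$out_dir, paste0("gsea_sum_", sc, ".tsv")),
      hdr(sprintf("engine: sumscore+prune  B: %d", config$sum_B)))
    write_tsv_with_header(
      tidy(cand_res, q_threshold = config$q_threshold),
      file.path(config$out_dir, paste0("gsea_candidate_", sc, ".tsv")),
      hdr(sprintf("engine: candidate  B: %d  percentile: %g",
                  config$cand_B, config$candidate_percentile)))
    write_tsv_with_header(
      tidy(disease[[sc]]),
      file.path(config$out_dir, paste0("disease_", sc, ".tsv")),
      hdr(sprintf("disease cutoff percentile: 1")))
  }

  manifest <- stage("manifest", {
    ins <- c(vcf = config$vcf, map = config$map, bed = config$bed,
             gmt = config$gmt, disease_list = config$disease_list)
    tibble(
      input = names(ins), path = unname(ins),
      md5 = unname(tools::md5sum(ins))
    )
  })
  write_tsv_with_header(manifest, file.path(config$out_dir, "manifest.tsv"),
                        hdr(sprintf("q threshold: %g", config$q_threshold)))

  invisible(list(panel = panel, scans = scans, gene_map = gene_map,
                 collections = collections, enrichment = enrichment,
                 disease = disease, manifest = manifest))
}
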