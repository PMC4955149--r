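#' Read a phased, polarized haplotype panel from a VCF
#'
#' Parses phased diploid genotypes from a VCF and recodes alleles so that
#' 0 is the ancestral allele, taken from an INFO annotation (default `AA`).
#' Records that are multiallelic, unphased, or lack a usable ancestral
#' annotation are rejected (strict mode) or dropped with a reported count
#' (lenient mode).
#'
#' @param vcf Path to an (uncompressed or bgzipped) VCF with phased `GT`.
#' @param populations Data frame with `sample_id` and `population`, or a
#'   named character vector `sample_id -> population`. Every listed sample
#'   must be present in the file.
#' @param aa_key INFO key holding the ancestral allele.
#' @param map Optional genetic map (see [read_genetic_map()]) used to
#'   interpolate genetic positions; without one, `cm` is filled assuming a
#'   flat 1 cM/Mb map.
#' @param strict If `TRUE` (default) any unusable record is an error; if
#'   `FALSE` such records are dropped and their count reported.
#' @return A [haplotype_panel()].
#' @export
read_haplotypes <- function(vcf, populations, aa_key = "AA", map = NULL,
                            strict = TRUE) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt[, -1, drop = FALSE]
  if (nrow(fix) == 0) abort("no parseable records in VCF")

  if (is.data.frame(populations)) {
    populations <- setNames(populations$population, populations$sample_id)
  }
  missing <- setdiff(names(populations), colnames(gt))
  if (length(missing)) {
    abort(paste("samples in population map missing from VCF:",
                paste(missing, collapse = ", ")))
  }
  gt <- gt[, names(populations), drop = FALSE]
  gt[] <- sub(":.*", "", gt)  # keep the GT field only

  info <- vcfR::getINFO(v)
  aa <- vapply(strsplit(info, ";", fixed = TRUE), function(kv) {
    hit <- kv[startsWith(kv, paste0(aa_key, "="))]
    if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
  }, character(1))

  bad_reason <- rep(NA_character_, nrow(fix))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  bad_reason[multi] <- "multiallelic"
  no_aa <- is.na(aa) | !(aa == fix[, "REF"] | aa == fix[, "ALT"])
  bad_reason[is.na(bad_reason) & no_aa] <- "no usable ancestral allele"
  unphased <- apply(gt, 1, function(g) any(!grepl("^[01]\\|[01]$", g)))
  bad_reason[is.na(bad_reason) & unphased] <- "unphased or missing genotype"

  if (strict && any(!is.na(bad_reason))) {
    i <- which(!is.na(bad_reason))[1]
    abort(sprintf("record %s:%s rejected (%s) in strict mode",
                  fix[i, "CHROM"], fix[i, "POS"], bad_reason[i]))
  }
  keep <- is.na(bad_reason)
  if (!any(keep)) abort("no usable records after filtering")
  if (any(!keep)) {
    inform(sprintf("dropped %d unusable record(s): %s", sum(!keep),
                   paste(unique(bad_reason[!keep]), collapse = "; ")))
  }

  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  aa <- aa[keep]
  alt_is_ancestral <- aa == fix[, "ALT"]

  # 2 haplotypes per sample, rows = haplotypes; recode so 0 = ancestral
  n_snp <- nrow(fix)
  n_sample <- ncol(gt)
  h1 <- matrix(as.integer(substr(gt, 1, 1)), n_snp, n_sample)
  h2 <- matrix(as.integer(substr(gt, 3, 3)), n_snp, n_sample)
  flip <- which(alt_is_ancestral)
  h1[flip, ] <- 1L - h1[flip, ]
  h2[flip, ] <- 1L - h2[flip, ]
  haps <- matrix(0L, 2L * n_sample, n_snp)
  haps[seq(1L, 2L * n_sample, 2L), ] <- t(h1)
  haps[seq(2L, 2L * n_sample, 2L), ] <- t(h2)

  pos <- as.integer(fix[, "POS"])
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%d", fix[, "CHROM"], pos)[is.na(ids) | ids == "."]
  snps <- tibble(
    snp_id = ids, chrom = fix[, "CHROM"], pos = pos,
    cm = if (is.null(map)) pos / 1e6 else
      interpolate_cm(map, fix[, "CHROM"], pos)
  )
  samples <- tibble(
    hap_id = paste0(rep(colnames(gt), each = 2), "_h", rep(1:2, n_sample)),
    sample_id = rep(colnames(gt), each = 2),
    population = rep(unname(populations), each = 2)
  )
  haplotype_panel(haps, snps, samples)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits one biallelic record per SNP with the ancestral allele in the
#' `AA` INFO field. To exercise polarity handling downstream, every third
#' record stores the ancestral allele as ALT (so `AA` is required to
#' recover polarity); [read_haplotypes()] inverts this losslessly.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  sample_ids <- unique(panel$samples$sample_id)
  n_snp <- nrow(panel$snps)
  swap <- seq_len(n_snp) %% 3L == 0L
  ref <- ifelse(swap, "G", "A")
  alt <- ifelse(swap, "A", "G")
  aa <- "A"  # ancestral base is always "A"; on swapped records it is ALT

  h <- panel$haplotypes  # 0 = ancestral
  gt_allele <- function(x, sw) if (sw) 1L - x else x  # VCF 0 = REF
  rows <- vapply(seq_len(n_snp), function(j) {
    a1 <- gt_allele(h[seq(1L, nrow(h), 2L), j], swap[j])
    a2 <- gt_allele(h[seq(2L, nrow(h), 2L), j], swap[j])
    paste(paste0(a1, "|", a2), collapse = "\t")
  }, character(1))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"),
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tAA=%s\tGT\t%s",
            panel$snps$chrom, panel$snps$pos, panel$snps$snp_id,
            ref, alt, aa, rows)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a genetic map
#'
#' Tab-separated table with columns `chrom`, `pos` (bp) and `cm`
#' (cumulative centimorgans); `cm` must be non-decreasing in position
#' within each chromosome. Genetic positions of query sites are obtained
#' by piecewise-linear interpolation; sites outside the mapped range are
#' clamped to the nearest endpoint with a warning.
#'
#' @param path Path to the map TSV (lines starting with `#` are ignored).
#' @return A tibble with `chrom`, `pos`, `cm`, of class `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  m <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("chrom", "pos", "cm") %in% names(m))) {
    abort("genetic map must have columns chrom, pos, cm")
  }
  m <- arrange(m, .data$chrom, .data$pos)
  bad <- m |> group_by(.data$chrom) |>
    summarise(ok = all(diff(.data$cm) >= 0) || n() < 2) |>
    filter(!.data$ok)
  if (nrow(bad)) {
    abort(paste("genetic map cM not non-decreasing on:",
                paste(bad$chrom, collapse = ", ")))
  }
  class(m) <- c("genetic_map", class(m))
  m
}

#' @rdname read_genetic_map
#' @param map A genetic map tibble.
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(as_tibble(map)[, c("chrom", "pos", "cm")], path)
  invisible(path)
}

#' Interpolate genetic positions from a map
#'
#' @param map A genetic map (see [read_genetic_map()]).
#' @param chrom Chromosome of each query position.
#' @param pos Physical positions (bp).
#' @return Genetic positions in cM (piecewise linear, clamped to the map
#'   range with a warning when queries fall outside it).
#' @export
interpolate_cm <- function(map, chrom, pos) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    sub <- map[map$chrom == ch, ]
    if (nrow(sub) < 2) abort(sprintf("map needs >= 2 points on %s", ch))
    if (any(pos[i] < min(sub$pos) | pos[i] > max(sub$pos))) {
      warn(sprintf("positions outside map range on %s clamped to endpoints", ch))
    }
    out[i] <- approx(sub$pos, sub$cm, xout = pos[i], rule = 2)$y
  }
  out
}

#' Read gene models from a BED file
#'
#' BED intervals (0-based, half-open) with the gene id in the name column;
#' one line per isoform. Coordinates are converted to the package-wide
#' 1-based inclusive convention at this boundary.
#'
#' @param path Path to the BED file.
#' @return A tibble of isoform intervals: `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @export
read_bed_genes <- function(path) {
  b <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                       show_col_types = FALSE)
  if (ncol(b) < 4) abort("BED file needs at least 4 columns (chrom, start, end, name)")
  tibble(
    gene_id = as.character(b[[4]]), chrom = as.character(b[[1]]),
    start = as.integer(b[[2]]) + 1L, end = as.integer(b[[3]])
  )
}

#' @rdname read_bed_genes
#' @param gene_models Tibble of 1-based inclusive isoform intervals.
#' @export
write_bed_genes <- function(gene_models, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", gene_models$chrom,
                     gene_models$start - 1L, gene_models$end,
                     gene_models$gene_id), path)
  invisible(path)
}

#' Read / write gene-set collections (GMT)
#'
#' One set per line: name, description, then member gene ids. Duplicate
#' gene ids within a set are collapsed; duplicate set names are an error.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) {
    abort(paste("duplicate gene-set names in GMT:",
                paste(unique(names(sets)[duplicated(names(sets))]),
                      collapse = ", ")))
  }
  lapply(sets, unique)
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors.
#' @param descriptions Optional per-set description column.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' @param path One gene id per line; `#` comments and blank lines ignored.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

# TSV writer with "# key: value" provenance header lines
write_tsv_with_header <- function(df, path, header = character(0)) {
  writeLines(paste0("# ", header), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
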