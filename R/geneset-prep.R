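#' Gene-set collection hygiene
#'
#' Prepares a raw gene-set collection for enrichment testing:
#' (1) members are restricted to genes that received at least one SNP;
#' (2) sets left with fewer than `min_size` genes are dropped;
#' (3) near-duplicate sets are merged greedily: while any pair of sets has
#' similarity above `merge_threshold`, the highest-similarity pair is
#' replaced by its union (names joined with `"+"`, lineage recorded);
#' (4) the size floor is re-applied. Ties in the greedy step are broken
#' lexicographically by set name, making the procedure deterministic and
#' independent of input order.
#'
#' Similarity is the Jaccard index by default; the overlap coefficient
#' (`|A&B| / min(|A|, |B|)`) is available via `similarity`.
#'
#' @param sets Named list of gene-id vectors.
#' @param scored_genes Character vector of genes with at least one
#'   assigned SNP (`NULL` skips the restriction).
#' @param min_size Minimum set size (default 10).
#' @param merge_threshold Similarity above which two sets are merged
#'   (default 0.95).
#' @param similarity `"jaccard"` or `"overlap"`.
#' @return A `geneset_collection`: list with `sets` (named list),
#'   `lineage` (tibble `set`, `merged_from`) and `log` (counts dropped at
#'   each stage).
#' @export
prepare_genesets <- function(sets, scored_genes = NULL, min_size = 10,
                             merge_threshold = 0.95,
                             similarity = c("jaccard", "overlap")) {
  similarity <- match.arg(similarity)
  if (!length(sets)) abort("empty gene-set collection")
  sets <- lapply(sets, unique)
  n_raw <- length(sets)

  if (!is.null(scored_genes)) {
    sets <- lapply(sets, intersect, y = scored_genes)
  }
  sets <- sets[order(names(sets))]
  small1 <- names(sets)[lengths(sets) < min_size]
  sets <- sets[lengths(sets) >= min_size]
  if (!length(sets)) abort("no gene set survives the size filter")

  sim_fun <- function(a, b) {
    i <- length(intersect(a, b))
    if (similarity == "jaccard") i / length(union(a, b)) else i / min(length(a), length(b))
  }
  lineage <- tibble(set = names(sets), merged_from = names(sets))
  repeat {
    nm <- names(sets)
    if (length(sets) < 2) break
    best <- c(0, NA, NA)
    for (i in seq_len(length(sets) - 1)) {
      for (j in (i + 1):length(sets)) {
        s <- sim_fun(sets[[i]], sets[[j]])
        if (s > best[1] + 1e-12) best <- c(s, i, j)
      }
    }
    if (best[1] <= merge_threshold) break
    i <- best[2]; j <- best[3]
    merged_name <- paste(sort(c(nm[i], nm[j])), collapse = "+")
    merged <- sort(union(sets[[i]], sets[[j]]))
    lineage <- bind_rows(
      filter(lineage, !.data$set %in% nm[c(i, j)]),
      tibble(set = merged_name,
             merged_from = lineage$merged_from[lineage$set %in% nm[c(i, j)]])
    )
    sets[[merged_name]] <- merged
    sets[nm[c(i, j)]] <- NULL
    sets <- sets[order(names(sets))]
  }

  small2 <- names(sets)[lengths(sets) < min_size]
  sets <- sets[lengths(sets) >= min_size]
  if (!length(sets)) abort("no gene set survives after merging")

  structure(
    list(sets = sets,
         lineage = filter(lineage, .data$set %in% names(sets)),
         log = list(n_raw = n_raw, dropped_small_pre = small1,
                    dropped_small_post = small2,
                    n_final = length(sets))),
    class = "geneset_collection"
  )
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("<geneset_collection> %d sets (from %d raw); sizes %d-%d\n",
              length(x$sets), x$log$n_raw,
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}
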