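#' Build the three annotated region classes from gene and island tables
#'
#' For each gene the TSS window spans 1 kb on each side of the transcription
#' start site and the gene body runs from 1 kb past the TSS to the
#' transcription end site, strand-aware:
#' * `+` strand, TSS `t`: TSS region `[t - 1000, t + 1000)`,
#'   gene body `[t + 1000, TES)`;
#' * `-` strand: mirrored (TSS at the gene end coordinate).
#'
#' Genes shorter than 2 kb yield a TSS region only (logged via a warning);
#' regions are clipped to chromosome bounds when lengths are supplied. CpG
#' islands are passed through as their own region class.
#'
#' @param genes Gene annotation data.frame (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`; 0-based half-open).
#' @param islands CpG-island data.frame (`chrom`, `start`, `end`) or `NULL`.
#' @param chrom_lengths Optional named vector for clipping.
#' @param tss_flank Half-width of the TSS window (default 1000 bases).
#' @return data.frame of `RegionDefinition`s: `region_id`, `class`
#'   (`TSS`, `gene_body`, `cpg_island`), `chrom`, `start`, `end`, `gene_id`,
#'   `strand`.
#' @export
build_regions <- function(genes, islands = NULL, chrom_lengths = NULL,
                          tss_flank = 1000L) {
  out <- list()
  if (!is.null(genes) && nrow(genes) > 0L) {
    if (any(genes$start >= genes$end)) stopf("gene start must be < end")
    tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    tes <- ifelse(genes$strand == "+", genes$end, genes$start)
    t_start <- tss - tss_flank
    t_end <- tss + tss_flank
    out$tss <- data.frame(
      region_id = paste0(genes$gene_id, "_TSS"), class = "TSS",
      chrom = genes$chrom, start = t_start, end = t_end,
      gene_id = genes$gene_id, strand = genes$strand, stringsAsFactors = FALSE
    )
    glen <- genes$end - genes$start
    has_body <- glen >= 2L * tss_flank
    if (any(!has_body)) {
      warnf("%d gene(s) shorter than %d bases: TSS region only, no gene body",
            sum(!has_body), 2L * tss_flank)
    }
    gb <- genes[has_body, , drop = FALSE]
    if (nrow(gb) > 0L) {
      b_start <- ifelse(gb$strand == "+", gb$start + tss_flank, gb$start)
      b_end <- ifelse(gb$strand == "+", gb$end, gb$end - tss_flank)
      out$body <- data.frame(
        region_id = paste0(gb$gene_id, "_body"), class = "gene_body",
        chrom = gb$chrom, start = b_start, end = b_end,
        gene_id = gb$gene_id, strand = gb$strand, stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(islands) && nrow(islands) > 0L) {
    out$isl <- data.frame(
      region_id = sprintf("cgi%04d", seq_len(nrow(islands))),
      class = "cpg_island", chrom = islands$chrom,
      start = islands$start, end = islands$end,
      gene_id = "", strand = "*", stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(region_id = character(), class = character(),
                      chrom = character(), start = integer(), end = integer(),
                      gene_id = character(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  regions <- do.call(rbind, out)
  rownames(regions) <- NULL
  if (!is.null(chrom_lengths)) {
    regions$start <- pmax(regions$start, 0L)
    lim <- chrom_lengths[regions$chrom]
    regions$end <- ifelse(is.na(lim), regions$end, pmin(regions$end, lim))
  } else {
    regions$start <- pmax(regions$start, 0L)
  }
  regions[regions$end > regions$start, , drop = FALSE]
}

#' Sum site counts into region read-count scores
#'
#' A region's score per sample is the sum of counts of sites whose C position
#' falls in `[start, end)`. A site inside two overlapping regions contributes
#' to both (no exclusive assignment).
#'
#' @param scm A `site_count_matrix`.
#' @param regions Region table from [build_regions()].
#' @return A `region_count_matrix`: list with `regions`, `counts` (region x
#'   sample), `lib_sizes` (per-sample library sizes inherited from `scm`).
#' @export
score_regions <- function(scm, regions) {
  stopifnot(inherits(scm, "site_count_matrix"))
  counts <- matrix(0L, nrow = nrow(regions), ncol = ncol(scm$counts),
                   dimnames = list(regions$region_id, colnames(scm$counts)))
  if (nrow(regions) > 0L && nrow(scm$sites) > 0L) {
    rg <- as_granges0(regions$chrom, regions$start, regions$end)
    sg <- site_granges(scm$sites)
    ov <- GenomicRanges::findOverlaps(sg, rg, ignore.strand = TRUE)
    si <- S4Vectors::queryHits(ov)
    ri <- S4Vectors::subjectHits(ov)
    if (length(si) > 0L) {
      agg <- rowsum(scm$counts[si, , drop = FALSE], group = ri)
      counts[as.integer(rownames(agg)), ] <- agg
    }
  }
  structure(list(regions = regions, counts = counts, lib_sizes = scm$lib_sizes),
            class = "region_count_matrix")
}

#' @export
print.region_count_matrix <- function(x, ...) {
  cat(sprintf("region_count_matrix: %d regions x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
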