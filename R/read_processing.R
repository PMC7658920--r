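#' Filter mapped reads on LpnPI-site offset
#'
#' A MeD-seq read is genuine enzyme product only if an LpnPI site (the C of a
#' CpG) sits at a characteristic distance from one of its ends. A read is kept
#' iff at least one candidate site lies at an offset within the closed window
#' `bounds` (default `[13, 17]` bases) from the 5' end **or** from the 3' end.
#' Offsets are computed from mapped coordinates against the site index:
#' `offset5 = site - start`, `offset3 = (start + length - 1) - site`.
#'
#' The kept read is assigned to the passing candidate site with the smallest
#' genomic position (ties across the window are resolved deterministically).
#'
#' @param reads data.frame of mapped reads: `read_id`, `chrom`, `start`
#'   (0-based), `length`, `strand`, optionally `sample`.
#' @param sites Site index data.frame (`chrom`, `pos`).
#' @param bounds Closed integer interval of accepted offsets.
#' @return list with `kept` (the kept reads plus `site_chrom`, `site_pos`) and
#'   `report` (totals: `input`, `kept`, `discarded`, and discard reasons
#'   `no_site_in_read`, `site_outside_window`). `kept + discarded == input`
#'   always.
#' @export
filter_reads <- function(reads, sites, bounds = c(13L, 17L)) {
  if (length(bounds) != 2L || bounds[1L] > bounds[2L]) {
    stopf("bounds must be an increasing pair")
  }
  n <- nrow(reads)
  report <- list(input = n, kept = 0L, discarded = n,
                 no_site_in_read = 0L, site_outside_window = 0L)
  kept_cols <- function(r) {
    r$site_chrom <- character(nrow(r)); r$site_pos <- integer(nrow(r)); r
  }
  if (n == 0L) {
    return(list(kept = kept_cols(reads), report = report))
  }
  if (any(reads$start < 0L) || any(reads$length <= 0L)) {
    stopf("mapped reads must have start >= 0 and length > 0")
  }
  hits <- read_site_hits(reads, sites)
  off5 <- hits$pos - hits$start
  off3 <- (hits$start + hits$length - 1L) - hits$pos
  pass <- (off5 >= bounds[1L] & off5 <= bounds[2L]) |
          (off3 >= bounds[1L] & off3 <= bounds[2L])
  had_site <- unique(hits$read_idx)
  ph <- hits[pass, , drop = FALSE]
  # smallest genomic position per read among passing candidates
  ph <- ph[order(ph$read_idx, ph$pos), , drop = FALSE]
  first <- !duplicated(ph$read_idx)
  keep_idx <- ph$read_idx[first]
  kept <- reads[keep_idx, , drop = FALSE]
  kept$site_chrom <- ph$chrom[first]
  kept$site_pos <- ph$pos[first]
  rownames(kept) <- NULL
  report$kept <- length(keep_idx)
  report$discarded <- n - report$kept
  report$no_site_in_read <- n - length(had_site)
  report$site_outside_window <- length(had_site) - report$kept
  list(kept = kept, report = report)
}

# all (read, candidate site) pairs where the site C lies inside the read span
read_site_hits <- function(reads, sites) {
  common <- union(unique(reads$chrom), unique(sites$chrom))
  r <- GenomicRanges::GRanges(
    seqnames = factor(reads$chrom, levels = common),
    ranges = IRanges::IRanges(start = reads$start + 1L,
                              width = reads$length)
  )
  s <- GenomicRanges::GRanges(
    seqnames = factor(sites$chrom, levels = common),
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
  ov <- GenomicRanges::findOverlaps(s, r, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(ov)
  ri <- S4Vectors::subjectHits(ov)
  data.frame(read_idx = ri,
             chrom = as.character(sites$chrom[si]),
             pos = sites$pos[si],
             start = reads$start[ri],
             length = reads$length[ri],
             stringsAsFactors = FALSE)
}

#' Tally filtered reads into the genome-wide site count matrix
#'
#' Each kept read increments exactly one site: the candidate that satisfied
#' the offset filter (smallest genomic position on ties, as recorded by
#' [filter_reads()]). Column sums of the result equal the per-sample kept-read
#' totals.
#'
#' @param kept Kept reads from [filter_reads()] (must carry `site_chrom`,
#'   `site_pos`; a `sample` column splits reads over samples, otherwise all
#'   reads form one sample named `"sample1"`).
#' @param sites Site index data.frame (`chrom`, `pos`), sorted.
#' @param samples Optional character vector fixing the sample columns (useful
#'   to keep empty samples in the matrix).
#' @return A `site_count_matrix`.
#' @export
assign_reads_to_sites <- function(kept, sites, samples = NULL) {
  if (!all(c("site_chrom", "site_pos") %in% names(kept))) {
    stopf("`kept` must come from filter_reads() (missing site assignment columns)")
  }
  assert_sites_sorted(sites)
  samp <- if ("sample" %in% names(kept)) as.character(kept$sample) else rep("sample1", nrow(kept))
  samples <- samples %||% (if (nrow(kept) > 0L) sort(unique(samp)) else "sample1")
  key <- paste(sites$chrom, sites$pos)
  idx <- match(paste(kept$site_chrom, kept$site_pos), key)
  if (anyNA(idx)) stopf("%d read(s) assigned to a site absent from the index", sum(is.na(idx)))
  tab <- table(factor(idx, levels = seq_len(nrow(sites))),
               factor(samp, levels = samples))
  counts <- matrix(as.integer(tab), nrow = nrow(sites),
                   dimnames = list(NULL, samples))
  site_count_matrix(sites, counts)
}
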