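# internal helpers shared across modules

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes its randomness through this
# so that identical seeds give byte-identical outputs.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# sites: data.frame(chrom, pos), 0-based position of the C of each CpG.
# Sorted means: chromosomes form contiguous blocks and positions increase
# within each block.
assert_sites_sorted <- function(sites) {
  r <- rle(as.character(sites$chrom))
  if (anyDuplicated(r$values)) {
    stopf("site index is not sorted: chromosome blocks are not contiguous")
  }
  ok <- vapply(split(sites$pos, factor(sites$chrom, levels = r$values)),
               function(p) !is.unsorted(p, strictly = TRUE), logical(1))
  if (!all(ok)) stopf("site index is not sorted by position within chromosome")
  invisible(TRUE)
}

# GRanges from 0-based half-open intervals (internal frame -> Bioconductor's
# 1-based closed frame). Zero-width intervals are dropped by the caller.
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.numeric(start) + 1, end = as.numeric(end))
  )
}

site_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = as.character(sites$chrom),
    ranges = IRanges::IRanges(start = sites$pos + 1, width = 1)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
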