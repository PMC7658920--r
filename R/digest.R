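#' Simulate LpnPI digestion of a methylated genome
#'
#' LpnPI cuts 16 bp downstream of a methylated CpG, releasing a 32-bp
#' fragment. The fragment convention is `[c - 16, c + 16)` on the forward
#' strand, i.e. the site's C sits at 5' offset 16 and the downstream cut falls
#' 16 bases past the C. Each site is emitted with probability equal to its
#' methylation fraction in the chosen sample; sites within 16 bases of a
#' chromosome end are skipped.
#'
#' @param genome A `genome_model`.
#' @param profile A `methylation_profile` covering the genome's sites.
#' @param sample Sample id (column of `profile$meth`).
#' @param seed Integer seed.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open;
#'   `end - start == 32` always) and `site` (0-based position of the C;
#'   `site - start == 16` always).
#' @export
digest_genome <- function(genome, profile, sample, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(profile, "methylation_profile"))
  if (!sample %in% colnames(profile$meth)) stopf("unknown sample '%s'", sample)
  sites <- profile$sites
  m <- profile$meth[, sample]
  chrom_len <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  eligible <- sites$pos >= 16L & sites$pos + 16L <= chrom_len[sites$chrom]
  emit <- with_seed(seed, stats::runif(nrow(sites)) < m) & eligible
  data.frame(
    chrom = sites$chrom[emit],
    start = sites$pos[emit] - 16L,
    end = sites$pos[emit] + 16L,
    site = sites$pos[emit],
    stringsAsFactors = FALSE
  )
}

#' Simulate 50-bp single-end reads from digestion fragments
#'
#' Each fragment yields one read. The 5' offset of the site's C within the
#' read is drawn uniformly from `offset_jitter` (default `[13, 17]`, the window
#' the read filter accepts; a wider jitter exercises both passing and failing
#' reads). The read sequence is the genomic sequence from `site - offset` up to
#' the fragment's downstream end, padded to `read_length` with `adapter_fill` —
#' emulating a 50-cycle run over a 32-bp insert with imperfect adapter
#' trimming.
#'
#' @param fragments Output of [digest_genome()].
#' @param genome The `genome_model` the fragments came from.
#' @param read_length Read length in nt (must be >= 32).
#' @param offset_jitter Integer range (length-2 vector) within `[0, 32]`.
#' @param adapter_fill Adapter sequence used to pad short inserts.
#' @param sample Sample id recorded in the truth table.
#' @param seed Integer seed.
#' @return list with `reads` (data.frame: `read_id`, `seq`, `qual`), `truth`
#'   (data.frame: `read_id`, `chrom`, `site`, `offset`, `start`, `sample`) and
#'   `mapped` (BED-like data.frame: `read_id`, `chrom`, `start`, `length`,
#'   `strand`, `sample`). One truth row per read, always.
#' @export
simulate_reads <- function(fragments, genome, read_length = 50L,
                           offset_jitter = c(13L, 17L),
                           adapter_fill = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                           sample = "sample1", seed = 1L) {
  if (read_length < 32L) stopf("read_length must be >= 32")
  if (length(offset_jitter) != 2L || offset_jitter[1L] > offset_jitter[2L] ||
      offset_jitter[1L] < 0L || offset_jitter[2L] > 32L) {
    stopf("offset_jitter must be an increasing pair within [0, 32]")
  }
  n <- nrow(fragments)
  empty <- list(
    reads = data.frame(read_id = character(), seq = character(),
                       qual = character(), stringsAsFactors = FALSE),
    truth = data.frame(read_id = character(), chrom = character(),
                       site = integer(), offset = integer(), start = integer(),
                       sample = character(), stringsAsFactors = FALSE),
    mapped = data.frame(read_id = character(), chrom = character(),
                        start = integer(), length = integer(),
                        strand = character(), sample = character(),
                        stringsAsFactors = FALSE)
  )
  if (n == 0L) return(empty)
  off <- with_seed(seed, {
    sample(seq.int(offset_jitter[1L], offset_jitter[2L]), n, replace = TRUE)
  })
  start <- fragments$site - off
  keep <- start >= 0L
  if (!all(keep)) {
    fragments <- fragments[keep, , drop = FALSE]
    off <- off[keep]
    start <- start[keep]
    n <- nrow(fragments)
    if (n == 0L) return(empty)
  }
  glen <- pmin(fragments$end - start, read_length)
  adapter <- paste(rep(adapter_fill, ceiling(read_length / nchar(adapter_fill))),
                   collapse = "")
  seqs <- substring(genome$sequences[fragments$chrom], start + 1L, start + glen)
  pad <- read_length - glen
  seqs <- paste0(seqs, substring(adapter, 1L, pad))
  read_id <- sprintf("%s_read%06d", sample, seq_len(n))
  list(
    reads = data.frame(read_id = read_id, seq = seqs,
                       qual = strrep("I", read_length), stringsAsFactors = FALSE),
    truth = data.frame(read_id = read_id, chrom = fragments$chrom,
                       site = fragments$site, offset = off, start = start,
                       sample = sample, stringsAsFactors = FALSE),
    mapped = data.frame(read_id = read_id, chrom = fragments$chrom,
                        start = start, length = read_length, strand = "+",
                        sample = sample, stringsAsFactors = FALSE)
  )
}
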