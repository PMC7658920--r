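#' Generate a synthetic multi-chromosome genome with CpG/LpnPI sites
#'
#' Builds a small genome model that stands in for a reference assembly in
#' simulations: random sequence with a controlled CpG-dinucleotide rate,
#' non-overlapping gene annotations (each at least 2 kb so that both the TSS
#' window and the gene body are non-empty) and CpG-island intervals.
#' All coordinates are 0-based half-open internally.
#'
#' LpnPI, the methylation-dependent restriction enzyme behind MeD-seq,
#' recognizes a CpG-containing site; here every CpG dinucleotide is treated as
#' a recognition site (see [locate_lpnpi_sites()]).
#'
#' @param lengths Integer vector of chromosome lengths in bases (one per
#'   chromosome). Zero-length chromosomes are allowed and yield no sites.
#' @param cpg_rate Target frequency of CG dinucleotide starts per base, in
#'   `[0, 0.5]`. The generator places `round(cpg_rate * length)` CG
#'   dinucleotides on a CG-free random background, so the realized rate matches
#'   the target up to rounding.
#' @param n_genes,n_islands Total numbers of gene and CpG-island annotations,
#'   distributed over chromosomes proportionally to length.
#' @param chrom_names Chromosome names; default `"chr1"`, `"chr2"`, ...
#' @param sex_chroms Character set of chromosome names to flag as sex
#'   chromosomes (e.g. `"chrX"`).
#' @param seed Integer seed; identical seeds and parameters give byte-identical
#'   genomes.
#' @return A `genome_model`: list with `chromosomes` (data.frame: `name`,
#'   `length`, `is_sex`), `sequences` (named character vector), `genes`
#'   (data.frame: `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`, `tes`)
#'   and `cpg_islands` (data.frame: `chrom`, `start`, `end`).
#' @seealso [genome_sites()], [generate_methylation_profiles()],
#'   [digest_genome()]
#' @export
generate_genome <- function(lengths,
                            cpg_rate = 0.05,
                            n_genes = 0L,
                            n_islands = 0L,
                            chrom_names = NULL,
                            sex_chroms = character(),
                            seed = 1L) {
  if (any(lengths < 0)) stopf("chromosome lengths must be >= 0")
  if (cpg_rate < 0 || cpg_rate > 0.5) stopf("cpg_rate must be in [0, 0.5]")
  if (n_genes < 0 || n_islands < 0) stopf("n_genes and n_islands must be >= 0")
  n_chrom <- length(lengths)
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_len(n_chrom))
  if (length(chrom_names) != n_chrom) stopf("need one name per chromosome")
  if (anyDuplicated(chrom_names)) stopf("duplicate chromosome names")

  with_seed(seed, {
    seqs <- vapply(lengths, random_chrom_sequence, character(1),
                   cpg_rate = cpg_rate)
    names(seqs) <- chrom_names

    genes <- place_genes(chrom_names, lengths, n_genes)
    islands <- place_islands(chrom_names, lengths, n_islands)

    structure(list(
      chromosomes = data.frame(
        name = chrom_names,
        length = as.integer(lengths),
        is_sex = chrom_names %in% sex_chroms,
        stringsAsFactors = FALSE
      ),
      sequences = seqs,
      genes = genes,
      cpg_islands = islands
    ), class = "genome_model")
  })
}

# Random sequence with an exact number of CG dinucleotides: draw an i.i.d.
# background, destroy accidental CGs (G -> A never creates a new CG), then
# stamp round(cpg_rate * len) CG blocks onto a non-overlapping grid of odd
# start positions (grid capacity (len-1)/2 matches the cpg_rate <= 0.5 bound).
random_chrom_sequence <- function(len, cpg_rate) {
  len <- as.integer(len)
  if (len == 0L) return("")
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (len >= 2L) {
    g_after_c <- which(s[-len] == "C" & s[-1L] == "G") + 1L
    s[g_after_c] <- "A"
    n_cg <- round(cpg_rate * len)
    grid <- seq.int(1L, len - 1L, by = 2L)
    n_cg <- min(n_cg, length(grid))
    if (n_cg > 0L) {
      at <- sort(sample(grid, n_cg))
      s[at] <- "C"
      s[at + 1L] <- "G"
    }
  }
  paste(s, collapse = "")
}

# Non-overlapping genes by slotting: each chromosome gets a share of genes
# proportional to length; its sequence is cut into equal slots and one gene is
# drawn inside each slot. Genes are >= 2 kb so TSS window and gene body are
# both non-empty.
place_genes <- function(chrom_names, lengths, n_genes) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      tss = integer(), tes = integer(), stringsAsFactors = FALSE)
  if (n_genes == 0L) return(empty)
  min_len <- 2000L
  usable <- lengths >= min_len + 500L
  if (!any(usable)) stopf("no chromosome is long enough to hold a gene")
  share <- lengths * usable
  alloc <- round(n_genes * share / sum(share))
  # fix rounding drift
  while (sum(alloc) > n_genes) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_genes) alloc[which.max(share / (alloc + 1))] <- alloc[which.max(share / (alloc + 1))] + 1L
  out <- list()
  gid <- 0L
  for (i in seq_along(lengths)) {
    k <- alloc[i]
    if (k <= 0L) next
    slot <- lengths[i] %/% k
    if (slot < min_len + 100L) {
      k <- max(1L, lengths[i] %/% (min_len + 100L))
      slot <- lengths[i] %/% k
    }
    for (j in seq_len(k)) {
      lo <- (j - 1L) * slot
      glen <- min_len + sample.int(max(1L, min(slot - min_len, 6000L)), 1L) - 1L
      glen <- min(glen, slot)
      start <- lo + sample.int(slot - glen + 1L, 1L) - 1L
      end <- start + glen
      strand <- sample(c("+", "-"), 1L)
      gid <- gid + 1L
      out[[length(out) + 1L]] <- data.frame(
        gene_id = sprintf("gene%04d", gid),
        chrom = chrom_names[i], strand = strand,
        start = start, end = end,
        tss = if (strand == "+") start else end,
        tes = if (strand == "+") end else start,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

place_islands <- function(chrom_names, lengths, n_islands) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (n_islands == 0L) return(empty)
  usable <- which(lengths >= 2000L)
  if (length(usable) == 0L) stopf("no chromosome is long enough to hold a CpG island")
  probs <- lengths[usable] / sum(lengths[usable])
  ci_chr <- usable[sample.int(length(usable), n_islands, replace = TRUE, prob = probs)]
  ilen <- sample(200:1000, n_islands, replace = TRUE)
  start <- vapply(seq_len(n_islands), function(k) {
    sample.int(lengths[ci_chr[k]] - ilen[k], 1L) - 1L
  }, integer(1))
  df <- data.frame(chrom = chrom_names[ci_chr], start = start,
                   end = start + ilen, stringsAsFactors = FALSE)
  df[order(match(df$chrom, chrom_names), df$start), , drop = FALSE]
}

#' Locate LpnPI recognition sites in a sequence
#'
#' Scans a DNA sequence for CpG dinucleotides and returns the 0-based position
#' of the C of each occurrence. The enzyme's recognition site is modeled as any
#' CpG; an exact-motif constraint can be layered on top by filtering the
#' returned positions.
#'
#' @param sequence A character scalar over `A,C,G,T,N` (or a
#'   `Biostrings::DNAString`). `N` never matches.
#' @return Sorted integer vector of 0-based positions; empty input gives an
#'   empty vector.
#' @examples
#' locate_lpnpi_sites("ACGT")  # 1
#' locate_lpnpi_sites("CGCG") # 0 2
#' @export
locate_lpnpi_sites <- function(sequence) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L) stopf("`sequence` must be a single string")
  if (nchar(sequence) < 2L) return(integer(0))
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Genome-wide LpnPI site index
#'
#' @param genome A `genome_model`.
#' @return data.frame with columns `chrom` and `pos` (0-based position of the
#'   C), sorted by chromosome (in genome order) then position.
#' @export
genome_sites <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  per <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    p <- locate_lpnpi_sites(genome$sequences[[i]])
    if (length(p) == 0L) return(NULL)
    data.frame(chrom = genome$chromosomes$name[i], pos = p,
               stringsAsFactors = FALSE)
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, per)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %s bases total\n",
              nrow(x$chromosomes), format(sum(x$chromosomes$length), big.mark = ",")))
  cat(sprintf("  genes: %d, CpG islands: %d, sex chromosomes: %s\n",
              nrow(x$genes), nrow(x$cpg_islands),
              if (any(x$chromosomes$is_sex)) paste(x$chromosomes$name[x$chromosomes$is_sex], collapse = ",") else "none"))
  invisible(x)
}
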