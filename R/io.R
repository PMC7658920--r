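#' Write a genome model as FASTA
#'
#' @param genome A `genome_model`.
#' @param path Output file.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_model"))
  seqs <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fasta")
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' @param reads data.frame with `read_id`, `seq`, `qual` (from
#'   [simulate_reads()]).
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$read_id
  Biostrings::writeXStringSet(
    s, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

#' Read a FASTQ file of simulated reads
#'
#' @param path FASTQ file.
#' @return data.frame with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(s), seq = as.character(s),
             qual = as.character(S4Vectors::mcols(s)$qualities),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df data.frame with `chrom`, `start`, `end`; optional `name`,
#'   `score`, `strand` columns fill BED columns 4-6.
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end)
  if (!is.null(df$name)) {
    bed$name <- df$name
    bed$score <- df$score %||% 0
    if (!is.null(df$strand)) bed$strand <- df$strand
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-site track as bedGraph
#'
#' One line per site, spanning the site's C, with the chosen value column —
#' loadable in a genome browser next to the called DMRs.
#'
#' @param sites data.frame with `chrom`, `pos`.
#' @param values Numeric vector (e.g. per-site `-log10(p)` or CPM).
#' @param path Output file.
#' @param track_name Track name written in the header line.
#' @export
write_bedgraph <- function(sites, values, path, track_name = "medseq") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  utils::write.table(
    data.frame(sites$chrom, sites$pos, sites$pos + 1L, values),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# header comment carrying provenance; parsed back by the loaders
provenance_header <- function(config = NULL, seed = NULL) {
  items <- c(
    sprintf("package=medseqr %s", as.character(utils::packageVersion("medseqr"))),
    if (!is.null(seed)) sprintf("seed=%s", seed),
    if (!is.null(config)) sprintf("config_hash=%s", config_hash(config))
  )
  paste0("# ", paste(items, collapse = " "))
}

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  # small stable rolling hash; provenance only, not cryptographic
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a DMR table in the published layout
#'
#' Mirrors the report layout: 1-based inclusive positions, fold change,
#' per-group methylation status, overlapping genes and position label. A
#' header comment records package version, seed and config hash.
#'
#' @param dmrs DMR data.frame (internal 0-based half-open `start`/`end`).
#' @param path Output file.
#' @param config,seed Optional provenance recorded in the header comment.
#' @export
write_dmr_table <- function(dmrs, path, config = NULL, seed = NULL) {
  out <- dmrs
  out$start <- out$start + 1L  # 1-based inclusive for human-facing tables
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config, seed), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Load a DMR table (published layout)
#'
#' Reads a tab-separated DMR table with 1-based inclusive positions and
#' converts coordinates to the internal 0-based half-open frame. Validation
#' is deliberately forgiving for anomalies present in printed tables: a
#' missing fold change and a start greater than its end are both ingested
#' as-is with a warning; the latter is flagged in `valid_interval` and such
#' records are skipped by interval-based operations.
#'
#' @param path Tab-separated file with columns `chrom`, `fold_change`,
#'   `start`, `end`, two `status_*` columns, `overlapping_genes`,
#'   `position_label`. `#`-prefixed header comments are skipped.
#' @return data.frame with internal coordinates plus `valid_interval`.
#' @export
load_dmr_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("chrom", "fold_change", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stopf("missing column(s) in %s: %s", path,
                               paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warnf("empty DMR table: %s", path)
  }
  df$chrom <- as.character(df$chrom)
  if (any(df$start < 1, na.rm = TRUE)) stopf("negative or zero 1-based coordinate in %s", path)
  df$valid_interval <- df$start <= df$end
  if (any(!df$valid_interval)) {
    warnf("%d record(s) with start > end ingested as-is (flagged valid_interval = FALSE)",
          sum(!df$valid_interval))
  }
  if (anyNA(df$fold_change)) {
    warnf("%d record(s) with missing fold change", sum(is.na(df$fold_change)))
  }
  if (!is.null(df$overlapping_genes)) {
    df$overlapping_genes[is.na(df$overlapping_genes)] <- ""
  }
  if (!is.null(df$position_label)) {
    df$position_label[is.na(df$position_label)] <- "none"
  }
  df$start <- df$start - 1L  # to 0-based half-open
  df
}

#' Load a probe-level expression table
#'
#' Reads the probe-level summary layout (`gene`, `probe`, `median`,
#' `iqr_low`, `iqr_high`, `p`), as shipped in the package's fixture of the
#' published validation table.
#'
#' @param path Tab-separated file.
#' @return data.frame, one row per probe.
#' @export
load_expression_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "probe")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stopf("missing column(s) in %s: %s", path,
                               paste(miss, collapse = ", "))
  df
}

#' Load a sample sheet
#'
#' @param path Tab-separated file with at least `sample_id` and `group`.
#' @return Validated data.frame.
#' @export
load_sample_sheet <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stopf("sample sheet must have 'sample_id' and 'group' columns")
  }
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample id in %s", path)
  if (!is.null(df$size_mm) && any(df$size_mm <= 0, na.rm = TRUE)) {
    stopf("size_mm must be > 0 when present")
  }
  df
}

#' Path to a bundled fixture table
#'
#' The package ships two small plain-text fixtures transcribed from the
#' study's printed tables: `"dmr"` — the ten reported DMRs with fold change
#' >= 1.5 (including one record with a missing fold change and one with
#' inverted coordinates, kept as printed); `"expression"` — the probe-level
#' expression validation summary.
#'
#' @param which `"dmr"` or `"expression"`.
#' @return File path.
#' @export
medseqr_fixture <- function(which = c("dmr", "expression")) {
  which <- match.arg(which)
  fn <- c(dmr = "dtf_dmr_table.tsv", expression = "dtf_expression_table.tsv")[[which]]
  system.file("extdata", fn, package = "medseqr", mustWork = TRUE)
}
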