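# small in-code fixtures shared across test files

# site count matrix from a bare count matrix; sites evenly spaced on chr1
# unless positions are given
toy_scm <- function(counts, pos = NULL, chrom = "chr1") {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = nrow(counts))
  site_count_matrix(
    data.frame(chrom = rep(chrom, nrow(counts)), pos = as.integer(pos),
               stringsAsFactors = FALSE),
    counts
  )
}

# region count matrix built directly (bypasses score_regions)
toy_rcm <- function(counts, lib_sizes, classes = "TSS") {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  n <- nrow(counts)
  regions <- data.frame(
    region_id = paste0("r", seq_len(n)), class = rep_len(classes, n),
    chrom = "chr1", start = seq(0L, by = 1000L, length.out = n),
    end = seq(1000L, by = 1000L, length.out = n),
    gene_id = paste0("g", seq_len(n)), strand = "+", stringsAsFactors = FALSE
  )
  structure(list(regions = regions, counts = counts,
                 lib_sizes = stats::setNames(lib_sizes, colnames(counts))),
            class = "region_count_matrix")
}

# two-group comparison over the columns of a matrix-like fixture
toy_groups <- function(n_a, n_b, ids = NULL) {
  ids <- ids %||% paste0("s", seq_len(n_a + n_b))
  make_groups(ids[seq_len(n_a)], ids[n_a + seq_len(n_b)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-enumeration oracle for the exact two-sided Mann-Whitney p-value:
# doubled lower tail of the enumerated U_x distribution at min(U_x, U_y)
mw_enum_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  ux_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u_obs <- min(ux_obs, n * m - ux_obs)
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  min(1, 2 * mean(us <= u_obs))
}

withr_local_tempfile <- function(env = parent.frame()) {
  withr::local_tempfile(.local_envir = env)
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# a small genome + profile + counts bundle for end-to-end style tests
toy_simulation <- function(seed = 1L, length = 40000L, n_inj = 4L,
                           fold_change = 2, n_sites = 8L,
                           hyper_group = c("S45F", "T41A"),
                           mean_depth = 30, noise_sd = 0.05,
                           n_s45f = 14L, n_t41a = 15L) {
  g <- generate_genome(c(chr1 = length), cpg_rate = 0.05, seed = seed)
  sheet <- generate_sample_sheet(n_s45f = n_s45f, n_t41a = n_t41a,
                                 seed = seed + 1000L)
  inj <- if (n_inj > 0L) {
    sample_injected_dmrs(g, n = n_inj, n_sites = n_sites,
                         fold_change = fold_change,
                         hyper_group = rep_len(hyper_group, n_inj),
                         min_separation = 40L, seed = seed + 2000L)
  }
  profile <- generate_methylation_profiles(g, sheet, inj, noise_sd = noise_sd,
                                           seed = seed + 3000L)
  scm <- simulate_site_counts(profile, mean_depth = mean_depth,
                              seed = seed + 4000L)
  list(genome = g, sheet = sheet, injected = inj, profile = profile,
       scm = scm, groups = groups_from_sheet(sheet))
}

# >= 50% reciprocal-overlap matching of called DMRs against a truth table;
# returns logical truth-matched vector and per-call true-positive flags
match_dmrs <- function(calls, truth) {
  matched <- logical(nrow(truth))
  tp <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ov <- pmin(calls$end[i], truth$end) - pmax(calls$start[i], truth$start)
    same <- calls$chrom[i] == truth$chrom
    rec <- same & ov >= 0.5 * (calls$end[i] - calls$start[i]) &
      ov >= 0.5 * (truth$end - truth$start)
    if (any(rec)) {
      matched[which(rec)[1L]] <- TRUE
      tp[i] <- TRUE
    }
  }
  list(matched = matched, tp = tp)
}
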