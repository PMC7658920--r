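#' Pearson chi-square test on a 2x2 read-count table
#'
#' The pipeline's core statistic: the Pearson chi-square with 1 degree of
#' freedom and no continuity correction, in closed form
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the p-value from the
#' chi-square survival function. The table compares a site's (or region's)
#' read count against the remainder of the library in each of two pooled
#' groups, which makes library-size normalization implicit.
#'
#' @param a,b,c,d Non-negative counts: row 1 = group A (in-feature,
#'   remainder), row 2 = group B.
#' @param correct Apply the Yates continuity correction (default off; counts
#'   in MeD-seq libraries are large).
#' @return list with `statistic` and `p.value`.
#' @examples
#' chisq_2x2(30, 70, 10, 90)$statistic  # 12.5
#' @export
chisq_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || anyNA(counts)) stopf("counts must be non-negative")
  if (min(a + b, c + d, a + c, b + d) == 0) {
    stopf("degenerate 2x2 table: zero row or column margin")
  }
  res <- chisq_2x2_vec(a, b, c, d, correct = correct)
  list(statistic = res$statistic, p.value = res$p.value)
}

# vectorized core; degenerate tables get statistic 0 / p 1 so that callers
# can skip them without branching
chisq_2x2_vec <- function(a, b, c, d, correct = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  dev <- abs(a * d - b * c)
  if (correct) dev <- pmax(0, dev - n / 2)
  stat <- ifelse(denom > 0, n * dev^2 / denom, 0)
  list(statistic = stat,
       p.value = ifelse(denom > 0, stats::pchisq(stat, df = 1, lower.tail = FALSE), 1),
       degenerate = denom == 0)
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up adjusted
#' p-values (via [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Per-site chi-square tests between two pooled groups
#'
#' For every site, tests the 2x2 table (group-A site count, group-A library
#' remainder; group-B site count, group-B library remainder). Degenerate
#' tables (e.g. a site with zero reads in both groups) are reported with
#' p = 1.
#'
#' @param scm A `site_count_matrix`.
#' @param groups A `group_comparison`.
#' @param correct Yates correction switch (default off).
#' @return data.frame: `chrom`, `pos`, `count_a`, `count_b`, `chi2`, `p`.
#' @export
site_chisq <- function(scm, groups, correct = FALSE) {
  stopifnot(inherits(scm, "site_count_matrix"),
            inherits(groups, "group_comparison"))
  miss <- setdiff(c(groups$a, groups$b), colnames(scm$counts))
  if (length(miss) > 0L) stopf("sample(s) absent from count matrix: %s",
                               paste(miss, collapse = ", "))
  xa <- rowSums(scm$counts[, groups$a, drop = FALSE])
  xb <- rowSums(scm$counts[, groups$b, drop = FALSE])
  la <- sum(scm$lib_sizes[groups$a])
  lb <- sum(scm$lib_sizes[groups$b])
  if (la == 0 || lb == 0) stopf("a group has zero total library size")
  res <- chisq_2x2_vec(xa, la - xa, xb, lb - xb, correct = correct)
  data.frame(chrom = scm$sites$chrom, pos = scm$sites$pos,
             count_a = xa, count_b = xb,
             chi2 = res$statistic, p = res$p.value,
             stringsAsFactors = FALSE)
}

#' Region-mode DMR detection
#'
#' Chi-square test per annotated region (TSS window, gene body or CpG island)
#' between two pooled groups: the 2x2 table is (in-region count, library
#' remainder) per group. Adjusted p-values below `alpha` define the candidate
#' DMRs.
#'
#' @param rcm A `region_count_matrix`.
#' @param groups A `group_comparison`.
#' @param alpha Significance level on the adjusted p-value.
#' @param method Correction method, `"BH"` or `"bonferroni"`.
#' @return data.frame of candidate DMRs (subset of the input regions) with
#'   `chi2`, `p`, `q`, `method` columns. Degenerate regions are skipped.
#' @export
test_regions <- function(rcm, groups, alpha = 0.05,
                         method = c("BH", "bonferroni")) {
  stopifnot(inherits(rcm, "region_count_matrix"),
            inherits(groups, "group_comparison"))
  method <- match.arg(method)
  xa <- rowSums(rcm$counts[, groups$a, drop = FALSE])
  xb <- rowSums(rcm$counts[, groups$b, drop = FALSE])
  la <- sum(rcm$lib_sizes[groups$a])
  lb <- sum(rcm$lib_sizes[groups$b])
  if (la == 0 || lb == 0) stopf("a group has zero total library size")
  res <- chisq_2x2_vec(xa, la - xa, xb, lb - xb)
  out <- rcm$regions
  out$count_a <- xa
  out$count_b <- xb
  out$chi2 <- res$statistic
  out$p <- res$p.value
  out <- out[!res$degenerate, , drop = FALSE]
  out$q <- adjust_pvalues(out$p, method)
  out$method <- method
  out <- out[out$q < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide sliding-window DMR detection
#'
#' Per-site chi-square tests between two pooled groups seed the window: sites
#' whose (by default BH-adjusted) p-value falls below `site_alpha` are
#' significant, and maximal runs of significant sites on one chromosome —
#' split wherever two consecutive significant sites lie more than `max_gap`
#' bases apart — are binned into one DMR. Runs with fewer than `min_sites`
#' sites are dropped. Each DMR's statistic and p-value are then recomputed on
#' its pooled counts, and adjusted across DMRs.
#'
#' Site-level correction (`site_correction = "BH"`) is the default because
#' uncorrected seeding at 0.05 over a genome-wide site index floods the
#' window with sporadic sites whose post-selection pooled p-values are badly
#' anti-conservative; `"none"` exposes the uncorrected variant (see the
#' methods vignette).
#'
#' DMR coordinates are 0-based half-open internally: `start` = first site C,
#' `end` = last site C + 1 (so 1-based inclusive output is `start + 1 .. end`).
#'
#' @param scm A `site_count_matrix` (site index must be sorted; error
#'   otherwise).
#' @param groups A `group_comparison`.
#' @param site_alpha Per-site seeding level, applied to the site p-value
#'   after `site_correction`.
#' @param site_correction Multiple-testing correction of the per-site
#'   p-values before seeding: `"BH"` (default), `"bonferroni"` or `"none"`.
#' @param min_sites Minimum LpnPI sites per reported DMR.
#' @param max_gap Maximum distance in bases between consecutive significant
#'   sites in one DMR. Scale this with the genome's site density (see the
#'   methods vignette); the default suits human CpG spacing.
#' @param method Multiple-testing correction applied across the binned DMRs.
#' @return data.frame of DMRs: `chrom`, `start`, `end`, `n_sites`, `count_a`,
#'   `count_b`, `chi2`, `p`, `q`, `method` — all runs, unfiltered on `q`;
#'   subset on `q` and pass through [compute_fold_change()] and
#'   [filter_dmrs()] to obtain the final calls.
#' @export
sliding_window_dmrs <- function(scm, groups, site_alpha = 0.05,
                                min_sites = 2L, max_gap = 1000L,
                                method = c("BH", "bonferroni"),
                                site_correction = c("BH", "bonferroni", "none")) {
  stopifnot(inherits(scm, "site_count_matrix"))
  method <- match.arg(method)
  site_correction <- match.arg(site_correction)
  if (min_sites < 1L) stopf("min_sites must be >= 1")
  assert_sites_sorted(scm$sites)
  st <- site_chisq(scm, groups)
  p_seed <- if (site_correction == "none") st$p else
    adjust_pvalues(st$p, site_correction)
  sig <- which(p_seed < site_alpha)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_sites = integer(), count_a = numeric(),
                      count_b = numeric(), chi2 = numeric(), p = numeric(),
                      q = numeric(), method = character(),
                      stringsAsFactors = FALSE)
  if (length(sig) == 0L) return(empty)
  chrom <- st$chrom[sig]
  pos <- st$pos[sig]
  new_run <- c(TRUE, chrom[-1L] != chrom[-length(chrom)] |
                 diff(pos) > max_gap)
  run_id <- cumsum(new_run)
  keep_runs <- which(tabulate(run_id) >= min_sites)
  if (length(keep_runs) == 0L) return(empty)
  la <- sum(scm$lib_sizes[groups$a])
  lb <- sum(scm$lib_sizes[groups$b])
  rows <- lapply(keep_runs, function(r) {
    i <- sig[run_id == r]
    xa <- sum(st$count_a[i])
    xb <- sum(st$count_b[i])
    data.frame(chrom = st$chrom[i[1L]],
               start = st$pos[i[1L]],
               end = st$pos[i[length(i)]] + 1L,
               n_sites = length(i), count_a = xa, count_b = xb,
               stringsAsFactors = FALSE)
  })
  dmrs <- do.call(rbind, rows)
  res <- chisq_2x2_vec(dmrs$count_a, la - dmrs$count_a,
                       dmrs$count_b, lb - dmrs$count_b)
  dmrs$chi2 <- res$statistic
  dmrs$p <- res$p.value
  dmrs$q <- adjust_pvalues(dmrs$p, method)
  dmrs$method <- method
  rownames(dmrs) <- NULL
  dmrs
}

#' Per-sample normalized read counts inside DMRs
#'
#' For each DMR, sums raw counts over contained sites per sample, adds the
#' pseudocount, and scales to counts per million by the sample's library size.
#' This is the value the fold change, Mann-Whitney comparison and clustering
#' all operate on.
#'
#' @param dmrs DMR data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param scm A `site_count_matrix`.
#' @param pseudocount Raw-count pseudocount added before normalization.
#' @return Numeric matrix, one row per DMR, one column per sample.
#' @export
dmr_site_values <- function(dmrs, scm, pseudocount = 0.5) {
  stopifnot(inherits(scm, "site_count_matrix"))
  raw <- matrix(0, nrow = nrow(dmrs), ncol = ncol(scm$counts),
                dimnames = list(NULL, colnames(scm$counts)))
  if (nrow(dmrs) > 0L && nrow(scm$sites) > 0L) {
    ok <- dmrs$end > dmrs$start
    if (any(ok)) {
      rg <- as_granges0(dmrs$chrom[ok], dmrs$start[ok], dmrs$end[ok])
      sg <- site_granges(scm$sites)
      ov <- GenomicRanges::findOverlaps(sg, rg, ignore.strand = TRUE)
      si <- S4Vectors::queryHits(ov)
      ri <- which(ok)[S4Vectors::subjectHits(ov)]
      if (length(si) > 0L) {
        agg <- rowsum(scm$counts[si, , drop = FALSE], group = ri)
        raw[as.integer(rownames(agg)), ] <- agg
      }
    }
  }
  sweep(raw + pseudocount, 2L, scm$lib_sizes, "/") * 1e6
}

#' Fold change and methylation status of DMRs
#'
#' Per group, averages the per-sample normalized in-DMR read counts (see
#' [dmr_site_values()]); the fold change is the larger group mean over the
#' smaller (always `>= 1`), the group with the larger mean is marked
#' hypermethylated (`"+"`), the other hypomethylated (`"-"`); exact ties give
#' fold change 1 and `"="` for both.
#'
#' @param dmrs DMR data.frame (`chrom`, `start`, `end`).
#' @param scm A `site_count_matrix`.
#' @param groups A `group_comparison`; its labels name the status columns
#'   (`status_<label>`).
#' @param pseudocount Raw-count pseudocount (default 0.5).
#' @return `dmrs` with `mean_a`, `mean_b`, `fold_change`, `hyper_group`,
#'   and two `status_*` columns added.
#' @export
compute_fold_change <- function(dmrs, scm, groups, pseudocount = 0.5) {
  stopifnot(inherits(groups, "group_comparison"))
  vals <- dmr_site_values(dmrs, scm, pseudocount = pseudocount)
  mean_a <- rowMeans(vals[, groups$a, drop = FALSE])
  mean_b <- rowMeans(vals[, groups$b, drop = FALSE])
  fc <- pmax(mean_a, mean_b) / pmin(mean_a, mean_b)
  status_a <- ifelse(mean_a > mean_b, "+", ifelse(mean_a < mean_b, "-", "="))
  status_b <- ifelse(mean_b > mean_a, "+", ifelse(mean_b < mean_a, "-", "="))
  dmrs$mean_a <- mean_a
  dmrs$mean_b <- mean_b
  dmrs$fold_change <- fc
  dmrs$hyper_group <- ifelse(status_a == "+", groups$labels[1L],
                             ifelse(status_b == "+", groups$labels[2L], NA))
  dmrs[[paste0("status_", groups$labels[1L])]] <- status_a
  dmrs[[paste0("status_", groups$labels[2L])]] <- status_b
  dmrs
}

#' Filter DMRs on fold change and sex chromosomes
#'
#' Keeps DMRs whose fold change meets the threshold (the study convention is
#' `>= 1.5`) and, when `exclude_sex` is set, whose canonical chromosome name
#' is not X or Y. Only exact canonical names (`X`, `Y`, `chrX`, `chrY`) are
#' excluded; alternate contigs such as `17_GL383563v3_alt` are retained.
#'
#' A record with a missing fold change behaves as if its fold change were
#' `na_fold_change` (default 1.5): appearing in a table whose inclusion rule
#' is "fold change >= 1.5" certifies that bound but nothing stricter, so such
#' records pass thresholds up to 1.5 and fail stricter ones.
#'
#' @param dmrs DMR data.frame with `chrom` and `fold_change`.
#' @param fc_threshold Minimum fold change (default 1.5).
#' @param exclude_sex Drop X/Y records (default `TRUE`).
#' @param sex_chroms Canonical sex-chromosome names.
#' @param na_fold_change Effective fold change of records with `NA` fold
#'   change.
#' @return The filtered data.frame.
#' @export
filter_dmrs <- function(dmrs, fc_threshold = 1.5, exclude_sex = TRUE,
                        sex_chroms = c("X", "Y", "chrX", "chrY"),
                        na_fold_change = 1.5) {
  fc <- dmrs$fold_change
  fc[is.na(fc)] <- na_fold_change
  keep <- fc >= fc_threshold
  if (exclude_sex) keep <- keep & !(dmrs$chrom %in% sex_chroms)
  out <- dmrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate DMRs with overlapping genes and region class
#'
#' A DMR overlapping any gene's TSS window is labeled `"TSS"`; one overlapping
#' only gene bodies is labeled `"postTSS1KB-TES"` (TSS takes precedence when
#' both overlap); a DMR with no gene overlap gets an empty gene list and label
#' `"none"`. CpG-island overlap is recorded as a separate flag.
#'
#' @param dmrs DMR data.frame (`chrom`, `start`, `end`, 0-based half-open).
#' @param regions Region table from [build_regions()].
#' @return `dmrs` with `overlapping_genes` (comma-joined, `""` if none),
#'   `position_label` and `cpg_island` columns added.
#' @export
annotate_dmrs <- function(dmrs, regions) {
  n <- nrow(dmrs)
  genes <- character(n)
  label <- rep("none", n)
  island <- logical(n)
  if (n > 0L && nrow(regions) > 0L) {
    ok <- which(dmrs$end > dmrs$start)
    if (length(ok) > 0L) {
      dg <- as_granges0(dmrs$chrom[ok], dmrs$start[ok], dmrs$end[ok])
      rg <- as_granges0(regions$chrom, regions$start, regions$end)
      ov <- GenomicRanges::findOverlaps(dg, rg, ignore.strand = TRUE)
      di <- ok[S4Vectors::queryHits(ov)]
      ri <- S4Vectors::subjectHits(ov)
      for (i in unique(di)) {
        r <- ri[di == i]
        cls <- regions$class[r]
        g <- unique(regions$gene_id[r][cls %in% c("TSS", "gene_body")])
        g <- g[g != ""]
        genes[i] <- paste(g, collapse = ",")
        label[i] <- if (any(cls == "TSS")) "TSS"
                    else if (any(cls == "gene_body")) "postTSS1KB-TES"
                    else "none"
        island[i] <- any(cls == "cpg_island")
      }
    }
  }
  dmrs$overlapping_genes <- genes
  dmrs$position_label <- label
  dmrs$cpg_island <- island
  dmrs
}

#' Full sliding-window DMR calling pipeline
#'
#' Convenience wrapper chaining [sliding_window_dmrs()], the adjusted-p cut,
#' [compute_fold_change()] and [filter_dmrs()] — the study's complete DMR
#' definition (significant after correction, fold change `>= fc_threshold`,
#' autosomal).
#'
#' @inheritParams sliding_window_dmrs
#' @inheritParams filter_dmrs
#' @param alpha Significance level applied to the DMR-level adjusted p.
#' @param pseudocount Passed to [compute_fold_change()].
#' @return Filtered, fold-change-annotated DMR data.frame.
#' @export
call_dmrs <- function(scm, groups, site_alpha = 0.05, min_sites = 2L,
                      max_gap = 1000L, method = c("BH", "bonferroni"),
                      site_correction = c("BH", "bonferroni", "none"),
                      alpha = 0.05, fc_threshold = 1.5, exclude_sex = TRUE,
                      pseudocount = 0.5) {
  method <- match.arg(method)
  site_correction <- match.arg(site_correction)
  dmrs <- sliding_window_dmrs(scm, groups, site_alpha = site_alpha,
                              min_sites = min_sites, max_gap = max_gap,
                              method = method,
                              site_correction = site_correction)
  dmrs <- dmrs[dmrs$q < alpha, , drop = FALSE]
  if (nrow(dmrs) == 0L) {
    dmrs$fold_change <- numeric(0)
    return(dmrs)
  }
  dmrs <- compute_fold_change(dmrs, scm, groups, pseudocount = pseudocount)
  filter_dmrs(dmrs, fc_threshold = fc_threshold, exclude_sex = exclude_sex)
}
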