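#' Mann-Whitney U test (two-sided)
#'
#' Computes U from ranks (`U` reported as the smaller of `U_x`, `U_y`, the
#' SPSS convention). The two-sided p-value is exact (doubled lower tail of the
#' null U distribution) when the samples are small (`min(n, m) <= 8` in
#' `"auto"` mode) and tie-free; otherwise a tie-corrected normal approximation
#' without continuity correction is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal"`. `"exact"` with ties falls
#'   back to the normal approximation with a warning.
#' @return list with `U`, `p.value`, `n`, `m`, and the `mode` actually used.
#' @examples
#' mannwhitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannwhitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stopf("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stopf("missing values not allowed")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  uy <- n * m - ux
  u <- min(ux, uy)
  ties <- anyDuplicated(c(x, y)) > 0L
  want_exact <- switch(mode,
                       auto = !ties && min(n, m) <= 8L,
                       exact = TRUE,
                       normal = FALSE)
  if (want_exact && ties) {
    warnf("ties present: falling back to the normal approximation")
    want_exact <- FALSE
  }
  if (want_exact) {
    p <- min(1, 2 * stats::pwilcox(u, n, m))
    used <- "exact"
  } else {
    N <- n + m
    tj <- table(r)
    tie_term <- sum(tj^3 - tj)
    v <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- (u - n * m / 2) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(z))  # u <= nm/2, so z <= 0
    }
    used <- "normal"
  }
  list(U = u, p.value = p, n = n, m = m, mode = used)
}

#' Per-DMR Mann-Whitney comparison of normalized read counts
#'
#' For each DMR, compares the per-sample normalized in-DMR read counts (see
#' [dmr_site_values()]) between the two groups; reports group medians, U and
#' the two-sided p-value with a significance flag at `alpha`.
#'
#' @param dmrs DMR data.frame (`chrom`, `start`, `end`).
#' @param scm A `site_count_matrix`.
#' @param groups A `group_comparison`.
#' @param alpha Significance level for the flag.
#' @param pseudocount Passed to [dmr_site_values()].
#' @return One row per input DMR: the DMR columns plus `median_a`, `median_b`,
#'   `U`, `p_mw`, `significant`.
#' @export
dmr_group_test <- function(dmrs, scm, groups, alpha = 0.05, pseudocount = 0.5) {
  stopifnot(inherits(groups, "group_comparison"))
  vals <- dmr_site_values(dmrs, scm, pseudocount = pseudocount)
  res <- lapply(seq_len(nrow(dmrs)), function(i) {
    xa <- vals[i, groups$a]
    xb <- vals[i, groups$b]
    mw <- mannwhitney_u(xa, xb)
    data.frame(median_a = stats::median(xa), median_b = stats::median(xb),
               U = mw$U, p_mw = mw$p.value)
  })
  res <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(median_a = numeric(), median_b = numeric(), U = numeric(),
               p_mw = numeric())
  out <- cbind(dmrs, res)
  out$significant <- out$p_mw < alpha
  rownames(out) <- NULL
  out
}

#' Supervised hierarchical clustering of samples on DMR methylation
#'
#' Clusters samples on their normalized in-DMR read counts, the construction
#' behind the study's heatmaps: DMRs are selected by a supervised contrast,
#' then all samples are clustered on those DMRs. Values are `log2(x + 1)`
#' transformed and z-scored per DMR before the distance computation
#' (zero-variance DMRs are dropped).
#'
#' @param values DMR x sample matrix of normalized values (e.g. from
#'   [dmr_site_values()]).
#' @param sample_sheet Optional sample sheet; covariate columns present among
#'   `group`, `sex`, `tumor_site`, `size_class` are summarized against the
#'   2-cluster cut.
#' @param linkage `hclust` agglomeration method: `"average"`, `"complete"` or
#'   `"ward.D2"`.
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson across DMRs).
#' @param transform Apply the log2/z-score standardization (default `TRUE`).
#' @return list with `tree` (`hclust`), `order` (sample ids in dendrogram
#'   order), `cut2` (named 2-cluster assignment) and `purity` (per-covariate
#'   data.frame: cluster purity of the 2-cut and, for binary covariates, the
#'   minimum number of misplaced samples).
#' @export
cluster_samples <- function(values, sample_sheet = NULL,
                            linkage = c("average", "complete", "ward.D2"),
                            metric = c("euclidean", "correlation"),
                            transform = TRUE) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  if (ncol(values) < 2L) stopf("need at least 2 samples to cluster")
  x <- values
  if (transform) {
    x <- log2(x + 1)
    mu <- rowMeans(x)
    sd <- apply(x, 1L, stats::sd)
    keep <- sd > 0
    x <- (x[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  }
  if (nrow(x) == 0L) stopf("no informative rows left after standardization")
  d <- if (metric == "euclidean") stats::dist(t(x))
       else stats::as.dist(1 - stats::cor(x))
  tree <- stats::hclust(d, method = linkage)
  cut2 <- stats::cutree(tree, k = 2L)
  purity <- NULL
  if (!is.null(sample_sheet)) {
    covs <- intersect(c("group", "sex", "tumor_site", "size_class"),
                      names(sample_sheet))
    sheet <- sample_sheet[match(colnames(values), sample_sheet$sample_id), ,
                          drop = FALSE]
    purity <- do.call(rbind, lapply(covs, function(cv) {
      v <- as.character(sheet[[cv]])
      ok <- !is.na(v)
      tab <- table(cut2[ok], v[ok])
      pur <- sum(apply(tab, 1L, max)) / sum(tab)
      mis <- NA_integer_
      if (ncol(tab) == 2L && nrow(tab) == 2L) {
        mis <- min(tab[1L, 1L] + tab[2L, 2L], tab[1L, 2L] + tab[2L, 1L])
      }
      data.frame(covariate = cv, purity = pur, misplaced = mis,
                 stringsAsFactors = FALSE)
    }))
  }
  list(tree = tree, order = colnames(values)[tree$order], cut2 = cut2,
       purity = purity)
}

#' DMR detection between size-extreme tumors
#'
#' Defines groups from the tumor-size covariate (small: `size_mm <=
#' small_max`; large: `size_mm > large_min`, defaults from the cohort's
#' printed IQR bounds 34 and 87 mm), excludes samples with missing size, and
#' delegates to the sliding-window DMR caller.
#'
#' @param scm A `site_count_matrix`.
#' @param sample_sheet Sample sheet with `sample_id` and `size_mm`.
#' @param small_max,large_min Size thresholds in millimeters.
#' @param ... Passed to [call_dmrs()].
#' @return The DMR data.frame from [call_dmrs()]; the groups used are
#'   attached as attribute `"groups"`.
#' @export
size_based_dmrs <- function(scm, sample_sheet, small_max = 34, large_min = 87,
                            ...) {
  sz <- sample_sheet$size_mm
  miss <- is.na(sz)
  if (any(miss)) {
    message(sprintf("excluding %d sample(s) with missing size", sum(miss)))
  }
  small <- sample_sheet$sample_id[!miss & sz <= small_max]
  large <- sample_sheet$sample_id[!miss & sz > large_min]
  if (length(small) < 2L || length(large) < 2L) {
    stopf("size thresholds (<= %s, > %s) leave fewer than 2 samples in a class",
          small_max, large_min)
  }
  groups <- make_groups(small, large, label_a = "small", label_b = "large")
  out <- call_dmrs(scm, groups, ...)
  attr(out, "groups") <- groups
  out
}

#' Write a clustering merge tree in newick format
#'
#' @param clustering Result of [cluster_samples()].
#' @param path Output file.
#' @export
write_tree_newick <- function(clustering, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stopf("newick export needs the 'ape' package")
  }
  ape::write.tree(ape::as.phylo(clustering$tree), file = path)
  invisible(path)
}

#' Probe-level expression validation of DMR-associated genes
#'
#' Mirrors the validation stage on an external expression matrix: for every
#' probe of every requested gene, reports the pooled median and IQR of the
#' expression values and a two-sided Mann-Whitney p-value between the two
#' groups. Genes without any probe are listed in the `"skipped_genes"`
#' attribute.
#'
#' @param expr Probe x sample numeric matrix (probe ids as rownames).
#' @param probe_map data.frame mapping `probe` to `gene`.
#' @param groups A `group_comparison` over the expression samples.
#' @param genes Character vector of gene symbols to validate.
#' @param alpha Significance level for the flag.
#' @return One row per probe: `gene`, `probe`, `median`, `iqr_low`,
#'   `iqr_high`, `U`, `p`, `significant`.
#' @export
expression_validation <- function(expr, probe_map, groups, genes,
                                  alpha = 0.05) {
  stopifnot(inherits(groups, "group_comparison"))
  miss <- setdiff(c(groups$a, groups$b), colnames(expr))
  if (length(miss) > 0L) stopf("sample(s) absent from expression matrix: %s",
                               paste(miss, collapse = ", "))
  pm <- probe_map[probe_map$gene %in% genes & probe_map$probe %in% rownames(expr), ,
                  drop = FALSE]
  skipped <- setdiff(genes, pm$gene)
  pm <- pm[order(match(pm$gene, genes)), , drop = FALSE]
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    v <- expr[pm$probe[i], ]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    mw <- mannwhitney_u(expr[pm$probe[i], groups$a], expr[pm$probe[i], groups$b])
    data.frame(gene = pm$gene[i], probe = pm$probe[i],
               median = stats::median(v), iqr_low = q[1L], iqr_high = q[2L],
               U = mw$U, p = mw$p.value, significant = mw$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene = character(), probe = character(), median = numeric(),
               iqr_low = numeric(), iqr_high = numeric(), U = numeric(),
               p = numeric(), significant = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped_genes") <- skipped
  out
}
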