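test_that("chisq_2x2 matches the hand formula and the stock implementation", {
  # proportional table: statistic 0, p 1
  r0 <- chisq_2x2(10, 90, 20, 180)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  # hand-computed Sum (O-E)^2/E with margin expectations
  r1 <- chisq_2x2(30, 70, 10, 90)
  expect_equal(r1$statistic, 12.5)
  expect_equal(r1$p.value, stats::pchisq(12.5, 1, lower.tail = FALSE))
  # row swap leaves the statistic unchanged
  expect_equal(chisq_2x2(10, 90, 30, 70)$statistic, r1$statistic)
  # independent oracle: stats::chisq.test without correction, random tables
  set.seed(41)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 50) + 1L, 2)
    ours <- chisq_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, unname(ref$p.value))
  }
  # Yates correction agrees with the stock implementation too
  ours_c <- chisq_2x2(12, 5, 3, 14, correct = TRUE)
  ref_c <- stats::chisq.test(matrix(c(12, 3, 5, 14), 2), correct = TRUE)
  expect_equal(ours_c$statistic, unname(ref_c$statistic))
  # degenerate margins error at the scalar interface
  expect_error(chisq_2x2(0, 0, 5, 5), "degenerate")
  expect_error(chisq_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("p-value adjustment reproduces hand-traced Bonferroni and BH", {
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  # step-up recursion by hand: all q equal 0.04
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.6, 0.7), "bonferroni"), c(1, 1))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  # BH q always within [p, 1] and monotone in rank
  set.seed(42)
  p <- runif(50)
  q <- adjust_pvalues(p, "BH")
  expect_true(all(q >= p & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("region-mode testing flags only truly shifted regions", {
  # null: identical per-region proportions in both groups -> no candidates
  base <- c(100L, 200L, 300L, 400L)
  counts <- cbind(a1 = base, a2 = base, b1 = 2L * base, b2 = 2L * base)
  rcm <- toy_rcm(counts, lib_sizes = colSums(counts) * 10)
  gr <- toy_groups(2, 2, colnames(counts))
  expect_identical(nrow(test_regions(rcm, gr)), 0L)
  # Monte-Carlo power: a 3-fold excess region at depth 50, 10 sites
  hits <- 0L
  for (s in 1:40) {
    set.seed(s)
    lam <- rep(500, 40)  # 10 sites x depth 50 per region-group
    xa <- rpois(40, lam * c(3, rep(1, 39)))
    xb <- rpois(40, lam)
    counts <- cbind(a = as.integer(xa), b = as.integer(xb))
    rcm <- toy_rcm(counts, lib_sizes = c(a = 1e6, b = 1e6))
    out <- test_regions(rcm, make_groups("a", "b"))
    hits <- hits + ("r1" %in% out$region_id)
    # candidate list is a subset of the input and q >= p under Bonferroni
    outb <- test_regions(rcm, make_groups("a", "b"), method = "bonferroni")
    expect_true(all(outb$region_id %in% rcm$regions$region_id))
    expect_true(all(outb$q >= outb$p))
  }
  expect_gte(hits / 40, 0.95)
})

test_that("sliding-window binning equals a brute-force run-length oracle", {
  # engineered flags: S S | gap > max_gap | S S S, plus null sites between
  pos <- c(100L, 160L, 400L, 3000L, 3060L, 3120L, 5000L)
  sig_pattern <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  na <- ifelse(sig_pattern, 5000L, 1000L)
  nb <- rep(1000L, length(pos))
  counts <- cbind(a = na, b = nb)
  scm <- toy_scm(counts, pos = pos)
  # pad library sizes so per-site tests are strongly significant where wanted
  scm$lib_sizes[] <- 1e6
  gr <- make_groups("a", "b")
  st <- site_chisq(scm, gr)
  expect_identical(st$p < 1e-4, sig_pattern)
  d <- sliding_window_dmrs(scm, gr, site_alpha = 1e-4, min_sites = 2L,
                           max_gap = 1000L, site_correction = "none")
  expect_identical(nrow(d), 2L)
  expect_identical(d$n_sites, c(2L, 3L))
  expect_identical(c(d$start, d$end), c(100L, 3000L, 161L, 3121L))
  # min_sites 3 keeps only the triple
  d3 <- sliding_window_dmrs(scm, gr, site_alpha = 1e-4, min_sites = 3L,
                            max_gap = 1000L, site_correction = "none")
  expect_identical(nrow(d3), 1L)
  expect_identical(d3$n_sites, 3L)
  # no significant site (all tables proportional) -> empty result
  null_scm <- toy_scm(cbind(a = rep(50L, 4), b = rep(100L, 4)))
  null_scm$lib_sizes[] <- c(1e5, 2e5)
  d0 <- sliding_window_dmrs(null_scm, gr, site_correction = "none")
  expect_identical(nrow(d0), 0L)
  # unsorted matrix errors
  bad <- scm
  bad$sites <- bad$sites[rev(seq_len(nrow(bad$sites))), ]
  expect_error(sliding_window_dmrs(bad, gr), "sorted")
})

test_that("sliding-window output ignores a prepended all-zero chromosome", {
  sim <- toy_simulation(seed = 8L, length = 20000L, n_inj = 2L)
  base <- sliding_window_dmrs(sim$scm, sim$groups, max_gap = 100L,
                              site_correction = "none")
  aug <- sim$scm
  zero_sites <- data.frame(chrom = "chr0", pos = seq(100L, 1000L, by = 100L),
                           stringsAsFactors = FALSE)
  aug$sites <- rbind(zero_sites, aug$sites)
  aug$counts <- rbind(matrix(0L, nrow = 10L, ncol = ncol(aug$counts),
                             dimnames = list(NULL, colnames(aug$counts))),
                      aug$counts)
  aug <- site_count_matrix(aug$sites, aug$counts)
  res <- sliding_window_dmrs(aug, sim$groups, max_gap = 100L,
                             site_correction = "none")
  expect_equal(res, base)
})

test_that("fold changes and statuses are oriented by the larger group mean", {
  # two sites, single DMR spanning them; S45F columns carry 2.68x the counts
  counts <- cbind(s45f_01 = c(268L, 268L), t41a_01 = c(100L, 100L))
  scm <- toy_scm(counts, pos = c(100L, 150L))
  scm$lib_sizes[] <- c(1e5, 1e5)
  dmr <- data.frame(chrom = "chr1", start = 100L, end = 151L)
  gr <- make_groups("s45f_01", "t41a_01")
  fc <- compute_fold_change(dmr, scm, gr, pseudocount = 0)
  expect_equal(fc$fold_change, 2.68)
  expect_identical(fc$status_S45F, "+")
  expect_identical(fc$status_T41A, "-")
  expect_identical(fc$hyper_group, "S45F")
  # direct ratio with pseudocount 0: means 30 vs 20 -> 1.5
  counts2 <- cbind(s45f_01 = 30L, t41a_01 = 20L)
  scm2 <- toy_scm(counts2, pos = 100L)
  scm2$lib_sizes[] <- c(1e6, 1e6)
  fc2 <- compute_fold_change(data.frame(chrom = "chr1", start = 100L, end = 101L),
                             scm2, gr, pseudocount = 0)
  expect_equal(fc2$fold_change, 1.5)
  # equal means tie
  counts3 <- cbind(s45f_01 = 30L, t41a_01 = 30L)
  scm3 <- toy_scm(counts3, pos = 100L)
  scm3$lib_sizes[] <- c(1e6, 1e6)
  fc3 <- compute_fold_change(data.frame(chrom = "chr1", start = 100L, end = 101L),
                             scm3, gr, pseudocount = 0)
  expect_equal(fc3$fold_change, 1)
  expect_identical(fc3$status_S45F, "=")
  expect_identical(fc3$status_T41A, "=")
})

test_that("swapping group labels inverts statuses and keeps fold changes", {
  sim <- toy_simulation(seed = 9L, length = 20000L, n_inj = 2L)
  dmrs <- sliding_window_dmrs(sim$scm, sim$groups, max_gap = 100L)
  fc_ab <- compute_fold_change(dmrs, sim$scm, sim$groups)
  swapped <- make_groups(sim$groups$b, sim$groups$a,
                         label_a = "T41A", label_b = "S45F")
  fc_ba <- compute_fold_change(dmrs, sim$scm, swapped)
  expect_equal(fc_ab$fold_change, fc_ba$fold_change)
  expect_identical(fc_ab$status_S45F, fc_ba$status_S45F)
  expect_identical(fc_ab$status_T41A, fc_ba$status_T41A)
})

test_that("DMR filtering applies fold-change and canonical sex-chromosome rules", {
  dmrs <- data.frame(
    chrom = c("1", "chrX", "X", "17_GL383563v3_alt", "2"),
    start = 1L, end = 100L,
    fold_change = c(2.0, 2.0, 2.0, 2.0, 1.2),
    stringsAsFactors = FALSE
  )
  out <- filter_dmrs(dmrs)
  expect_identical(out$chrom, c("1", "17_GL383563v3_alt"))
  # threshold 1.0 without sex exclusion is the identity
  expect_identical(nrow(filter_dmrs(dmrs, fc_threshold = 1,
                                    exclude_sex = FALSE)), 5L)
  # sex exclusion off keeps the X records
  expect_identical(nrow(filter_dmrs(dmrs, exclude_sex = FALSE)), 4L)
})

test_that("annotation labels match a brute-force overlap classification", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = c("+", "-"), start = c(5000L, 20000L),
                      end = c(12000L, 26000L), stringsAsFactors = FALSE)
  islands <- data.frame(chrom = "chr1", start = 7000L, end = 7500L,
                        stringsAsFactors = FALSE)
  regions <- build_regions(genes, islands)
  dmrs <- data.frame(
    chrom = "chr1",
    start = c(8000L, 4500L, 15000L, 7100L, 25500L),
    end = c(8100L, 4600L, 15100L, 7200L, 25600L),
    stringsAsFactors = FALSE
  )
  ann <- annotate_dmrs(dmrs, regions)
  # inside gA body; inside gA TSS window; intergenic; body+island; gB TSS (minus strand)
  expect_identical(ann$position_label,
                   c("postTSS1KB-TES", "TSS", "none", "postTSS1KB-TES", "TSS"))
  expect_identical(ann$overlapping_genes, c("gA", "gA", "", "gA", "gB"))
  expect_identical(ann$cpg_island, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  # randomized brute-force oracle
  set.seed(51)
  rdmrs <- data.frame(chrom = "chr1",
                      start = sample(0:29000, 40), stringsAsFactors = FALSE)
  rdmrs$end <- rdmrs$start + sample(50:3000, 40, replace = TRUE)
  got <- annotate_dmrs(rdmrs, regions)
  for (i in seq_len(nrow(rdmrs))) {
    ov <- regions$start < rdmrs$end[i] & regions$end > rdmrs$start[i]
    cls <- regions$class[ov]
    want <- if (any(cls == "TSS")) "TSS"
            else if (any(cls == "gene_body")) "postTSS1KB-TES" else "none"
    expect_identical(got$position_label[i], want)
    expect_identical(got$cpg_island[i], any(cls == "cpg_island"))
  }
})
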