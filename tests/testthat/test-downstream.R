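test_that("Mann-Whitney U and exact p match full enumeration", {
  r <- mannwhitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 0.1)
  expect_identical(r$mode, "exact")
  # identical multisets: U = nm/2, p ~ 1 (tie fallback to normal)
  r2 <- suppressWarnings(mannwhitney_u(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r2$U, 4.5)
  expect_gte(r2$p.value, 0.99)
  # random tie-free small vectors against the enumeration oracle
  set.seed(61)
  for (i in 1:8) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    v <- sample(1000L, n + m)  # distinct values, no ties
    x <- v[seq_len(n)]; y <- v[n + seq_len(m)]
    r <- mannwhitney_u(x, y)
    ux <- sum(rank(c(x, y))[seq_len(n)]) - n * (n + 1) / 2
    expect_equal(r$U, min(ux, n * m - ux))
    expect_equal(r$p.value, mw_enum_oracle(x, y))
    # and against the stock two-sided exact test
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(r$p.value, ref$p.value)
  }
  expect_error(mannwhitney_u(numeric(0), 1), "non-empty")
})

test_that("tie-corrected normal approximation is sane on large samples", {
  set.seed(62)
  x <- rnorm(60); y <- rnorm(70) + 2
  r <- mannwhitney_u(x, y)
  expect_identical(r$mode, "normal")
  expect_lt(r$p.value, 1e-6)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(r$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("per-DMR group tests conserve rows and detect injected shifts", {
  sim <- toy_simulation(seed = 10L, length = 30000L, n_inj = 3L,
                        fold_change = 3, mean_depth = 50, noise_sd = 0.02)
  dmrs <- sim$injected[, c("chrom", "start", "end")]
  res <- dmr_group_test(dmrs, sim$scm, sim$groups)
  expect_identical(nrow(res), nrow(dmrs))
  expect_true(all(res$p_mw < 0.05))
  # identical per-sample values in both groups -> p ~ 1
  counts <- matrix(10L, nrow = 2, ncol = 8,
                   dimnames = list(NULL, paste0("s", 1:8)))
  scm <- toy_scm(counts, pos = c(100L, 200L))
  null <- dmr_group_test(data.frame(chrom = "chr1", start = 100L, end = 201L),
                         scm, toy_groups(4, 4))
  expect_gte(null$p_mw, 0.99)
})

test_that("injected 3-fold DMRs are flagged across seeds", {
  hits <- 0L
  n_seeds <- 15L
  for (s in seq_len(n_seeds)) {
    sim <- toy_simulation(seed = 100L + s, length = 15000L, n_inj = 1L,
                          fold_change = 3, mean_depth = 30, noise_sd = 0.05)
    res <- dmr_group_test(sim$injected[, c("chrom", "start", "end")],
                          sim$scm, sim$groups)
    hits <- hits + (res$p_mw[1] < 0.05)
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("clustering merges identical samples first and is permutation-stable", {
  set.seed(63)
  base <- matrix(rexp(40, 0.1), nrow = 10)
  vals <- cbind(base, base[, 1])  # column 5 duplicates column 1
  colnames(vals) <- paste0("s", 1:5)
  cl <- cluster_samples(vals, transform = FALSE)
  expect_equal(cl$tree$height[1], 0)
  first_pair <- sort(abs(cl$tree$merge[1, ]))
  expect_identical(colnames(vals)[first_pair], c("s1", "s5"))
  # hand-traced 3-sample complete-linkage agglomeration
  v3 <- matrix(c(0, 0, 1, 0, 3, 0), nrow = 2)  # d12 = 1, d13 = 3, d23 = 2
  colnames(v3) <- c("a", "b", "c")
  cl3 <- cluster_samples(v3, linkage = "complete", transform = FALSE)
  expect_equal(cl3$tree$height, c(1, 3))
  expect_identical(sort(abs(cl3$tree$merge[1, ])), c(1L, 2L))
  # column permutation does not change the merge heights
  perm <- c(3, 1, 4, 2, 5)
  clp <- cluster_samples(vals[, perm], transform = FALSE)
  expect_equal(sort(clp$tree$height), sort(cl$tree$height))
  expect_error(cluster_samples(vals[, 1, drop = FALSE]), "2 samples")
})

test_that("size-extreme grouping validates thresholds and sample counts", {
  sim <- toy_simulation(seed = 12L, length = 20000L, n_inj = 0L)
  sheet <- sim$sheet
  sheet$size_mm <- c(seq(20, 40, length.out = 14), seq(80, 130, length.out = 15))
  expect_error(size_based_dmrs(sim$scm, sheet, small_max = 1, large_min = 87),
               "fewer than 2")
  out <- size_based_dmrs(sim$scm, sheet, small_max = 34, large_min = 87,
                         max_gap = 100L)
  gr <- attr(out, "groups")
  expect_identical(gr$labels, c("small", "large"))
  expect_true(all(sheet$size_mm[match(gr$a, sheet$sample_id)] <= 34))
  expect_true(all(sheet$size_mm[match(gr$b, sheet$sample_id)] > 87))
  # null simulation: no size-driven signal -> no DMRs
  expect_identical(nrow(out), 0L)
  # missing sizes are excluded with a message
  sheet$size_mm[1] <- NA
  expect_message(size_based_dmrs(sim$scm, sheet, max_gap = 100L), "missing size")
})

test_that("expression validation reports one row per probe with pooled summaries", {
  set.seed(64)
  samples <- paste0("e", 1:20)
  probes <- c("p1a", "p1b", "p2a", "p3a", "p3b", "p3c", "p3d")
  expr <- matrix(rnorm(length(probes) * 20, 100, 10), nrow = length(probes),
                 dimnames = list(probes, samples))
  map <- data.frame(probe = probes,
                    gene = c("G1", "G1", "G2", "G3", "G3", "G3", "G3"),
                    stringsAsFactors = FALSE)
  gr <- make_groups(samples[1:10], samples[11:20])
  res <- expression_validation(expr, map, gr, c("G3", "G1", "MISSING"))
  expect_identical(nrow(res), 6L)  # 4 probes for G3 + 2 for G1
  expect_identical(sum(res$gene == "G3"), 4L)
  expect_identical(attr(res, "skipped_genes"), "MISSING")
  # constant expression: median = constant, IQR degenerate, p ~ 1
  expr["p2a", ] <- 42
  res2 <- suppressWarnings(expression_validation(expr, map, gr, "G2"))
  expect_equal(res2$median, 42)
  expect_equal(c(res2$iqr_low, res2$iqr_high), c(42, 42))
  expect_gte(res2$p, 0.99)
})

test_that("expression p-values are calibrated under the null", {
  set.seed(65)
  n_probes <- 400L
  samples <- paste0("e", 1:79)
  expr <- matrix(rnorm(n_probes * 79), nrow = n_probes,
                 dimnames = list(sprintf("p%03d", seq_len(n_probes)), samples))
  map <- data.frame(probe = rownames(expr), gene = "G",
                    stringsAsFactors = FALSE)
  gr <- make_groups(samples[1:34], samples[35:79])
  res <- expression_validation(expr, map, gr, "G")
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_probes) + 0.01)
})

test_that("the clustering merge tree exports as parseable newick", {
  set.seed(66)
  vals <- matrix(rexp(40, 0.1), nrow = 10,
                 dimnames = list(NULL, paste0("s", 1:4)))
  cl <- cluster_samples(vals, transform = FALSE)
  tmp <- withr_local_tempfile()
  write_tree_newick(cl, tmp)
  tree <- ape::read.tree(tmp)
  expect_setequal(tree$tip.label, colnames(vals))
})
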