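#' Pipeline configuration with the study's printed constants
#'
#' Collects every tunable of the pipeline in one validated list: the read
#' filter bounds (13-17 bp), the 32-bp fragment length with its 16-bp cut
#' offset, the 1-kb TSS flank, the 0.05 significance level with its
#' correction method, the 1.5 fold-change cut, the sliding-window knobs and
#' the synthetic-generator parameters. Override any field by name.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated `medseq_config` list.
#' @export
medseq_config <- function(...) {
  config <- list(
    seed = 1L,
    # synthetic genome
    chrom_lengths = c(chr1 = 60000L, chr2 = 40000L),
    cpg_rate = 0.05,
    n_genes = 20L,
    n_islands = 10L,
    sex_chroms = character(),
    # cohort
    n_s45f = 14L, n_t41a = 15L,
    # methylation / counts
    baseline_mean = 0.3, noise_sd = 0.05,
    mean_depth = 30, dispersion = 0,
    # injected truth
    n_injected = 5L, injected_fold_change = 2, injected_n_sites = 8L,
    # read geometry / filter
    read_length = 50L, fragment_length = 32L, cut_offset = 16L,
    filter_bounds = c(13L, 17L), offset_jitter = c(13L, 17L),
    # regions
    tss_flank = 1000L,
    # detection
    alpha = 0.05, site_alpha = 0.05, correction = "BH",
    fc_threshold = 1.5, min_sites = 2L, max_gap = 100L, pseudocount = 0.5,
    exclude_sex = TRUE,
    normalization = "CPM"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(config))
  if (length(unknown) > 0L) stopf("unknown config field(s): %s",
                                  paste(unknown, collapse = ", "))
  config[names(over)] <- over
  validate_config(config)
  structure(config, class = "medseq_config")
}

validate_config <- function(config) {
  chk <- function(cond, msg) if (!cond) stopf("invalid config: %s", msg)
  chk(config$cpg_rate >= 0 && config$cpg_rate <= 0.5, "cpg_rate outside [0, 0.5]")
  chk(config$baseline_mean > 0 && config$baseline_mean < 1, "baseline_mean outside (0, 1)")
  chk(config$noise_sd >= 0, "noise_sd < 0")
  chk(config$mean_depth > 0, "mean_depth <= 0")
  chk(config$dispersion >= 0, "dispersion < 0")
  chk(config$read_length >= config$fragment_length, "read_length < fragment_length")
  chk(config$filter_bounds[1L] <= config$filter_bounds[2L], "filter bounds not increasing")
  chk(config$alpha > 0 && config$alpha <= 1, "alpha outside (0, 1]")
  chk(config$site_alpha > 0 && config$site_alpha <= 1, "site_alpha outside (0, 1]")
  chk(config$correction %in% c("BH", "bonferroni"), "unknown correction method")
  chk(config$fc_threshold >= 1, "fc_threshold < 1")
  chk(config$min_sites >= 1, "min_sites < 1")
  chk(config$max_gap >= 0, "max_gap < 0")
  chk(config$pseudocount >= 0, "pseudocount < 0")
  invisible(config)
}

#' Run the synthetic end-to-end pipeline
#'
#' Chains the stages simulate -> count -> detect -> downstream on fully
#' synthetic data: genome and cohort generation, methylation profiles with
#' injected differential regions, per-site counts, sliding-window DMR
#' detection with correction and fold-change/sex filtering, DMR annotation
#' against the generated gene/island regions, the per-DMR Mann-Whitney test
#' and the supervised sample clustering. Identical config and seed reproduce
#' every output.
#'
#' @param config A `medseq_config`.
#' @param out_dir Optional directory; when given, the DMR table (TSV, 1-based
#'   inclusive), a BED5 version, and a per-site p-value bedGraph are written
#'   there with provenance headers.
#' @return list with `genome`, `sample_sheet`, `truth`, `scm`, `site_tests`,
#'   `dmrs` (annotated, tested), `clustering`, and `report` (per-stage record
#'   counts, parameters, seed).
#' @export
run_pipeline <- function(config = medseq_config(), out_dir = NULL) {
  stopifnot(inherits(config, "medseq_config"))
  seed <- as.integer(config$seed)
  genome <- generate_genome(config$chrom_lengths, cpg_rate = config$cpg_rate,
                            n_genes = config$n_genes,
                            n_islands = config$n_islands,
                            chrom_names = names(config$chrom_lengths),
                            sex_chroms = config$sex_chroms, seed = seed)
  sheet <- generate_sample_sheet(config$n_s45f, config$n_t41a, seed = seed + 1L)
  injected <- if (config$n_injected > 0L) {
    sample_injected_dmrs(genome, n = config$n_injected,
                         n_sites = config$injected_n_sites,
                         fold_change = config$injected_fold_change,
                         hyper_group = "S45F", seed = seed + 2L)
  }
  profile <- generate_methylation_profiles(genome, sheet, injected,
                                           baseline_mean = config$baseline_mean,
                                           noise_sd = config$noise_sd,
                                           seed = seed + 3L)
  scm <- simulate_site_counts(profile, mean_depth = config$mean_depth,
                              dispersion = config$dispersion, seed = seed + 4L)
  groups <- groups_from_sheet(sheet)
  site_tests <- site_chisq(scm, groups)
  dmrs <- call_dmrs(scm, groups, site_alpha = config$site_alpha,
                    min_sites = config$min_sites, max_gap = config$max_gap,
                    method = config$correction, alpha = config$alpha,
                    fc_threshold = config$fc_threshold,
                    exclude_sex = config$exclude_sex,
                    pseudocount = config$pseudocount)
  regions <- build_regions(genome$genes, genome$cpg_islands,
                           chrom_lengths = stats::setNames(genome$chromosomes$length,
                                                           genome$chromosomes$name),
                           tss_flank = config$tss_flank)
  dmrs <- annotate_dmrs(dmrs, regions)
  dmrs <- dmr_group_test(dmrs, scm, groups, alpha = config$alpha,
                         pseudocount = config$pseudocount)
  clustering <- if (nrow(dmrs) >= 2L) {
    cluster_samples(dmr_site_values(dmrs, scm, config$pseudocount), sheet)
  }
  report <- list(
    seed = seed,
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    stages = data.frame(
      stage = c("genome_sites", "samples", "injected", "counted_sites", "dmrs"),
      records = c(nrow(scm$sites), nrow(sheet),
                  if (is.null(injected)) 0L else nrow(injected),
                  nrow(scm$counts), nrow(dmrs)),
      stringsAsFactors = FALSE
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dmr_table(dmrs, file.path(out_dir, "dmrs.tsv"),
                    config = unclass(config), seed = seed)
    if (nrow(dmrs) > 0L) {
      write_bed(data.frame(chrom = dmrs$chrom, start = dmrs$start,
                           end = dmrs$end,
                           name = sprintf("DMR%03d", seq_len(nrow(dmrs))),
                           score = round(-10 * log10(pmax(dmrs$q, 1e-300)))),
                file.path(out_dir, "dmrs.bed"))
    }
    write_bedgraph(scm$sites, -log10(pmax(site_tests$p, 1e-300)),
                   file.path(out_dir, "site_pvalues.bedGraph"),
                   track_name = "medseq_site_mlog10p")
  }
  list(genome = genome, sample_sheet = sheet, truth = profile$truth,
       scm = scm, site_tests = site_tests, dmrs = dmrs,
       clustering = clustering, report = report)
}
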