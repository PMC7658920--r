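#' Sample ground-truth differential regions over a synthetic genome
#'
#' Picks non-overlapping runs of consecutive LpnPI sites and turns each into an
#' injected differentially methylated region with a target fold change and a
#' hypermethylated group. Runs are kept well separated (`min_separation`
#' intervening sites) so that injected regions cannot merge during detection.
#'
#' @param genome A `genome_model`.
#' @param n Number of regions to inject.
#' @param n_sites Consecutive LpnPI sites per region.
#' @param fold_change Target group-mean ratio (recycled), each `>= 1`.
#' @param hyper_group Label of the hypermethylated group for each region
#'   (recycled), e.g. `"S45F"`.
#' @param min_separation Minimum number of sites between chosen runs.
#' @param seed Integer seed.
#' @return data.frame (`injected_dmr_truth`) with columns `chrom`, `start`,
#'   `end` (0-based half-open, covering the run of site Cs), `fold_change`,
#'   `hyper_group`, `n_sites`.
#' @export
sample_injected_dmrs <- function(genome, n, n_sites = 8L, fold_change = 2,
                                 hyper_group = "S45F", min_separation = 50L,
                                 seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (any(fold_change < 1)) stopf("fold_change must be >= 1")
  sites <- genome_sites(genome)
  if (nrow(sites) < n * (n_sites + min_separation)) {
    stopf("genome has too few LpnPI sites for %d regions of %d sites", n, n_sites)
  }
  fold_change <- rep_len(fold_change, n)
  hyper_group <- rep_len(hyper_group, n)
  with_seed(seed, {
    # choose run start indices on a site grid with fixed pitch, then jitter
    pitch <- n_sites + min_separation
    n_slots <- nrow(sites) %/% pitch
    slots <- sort(sample.int(n_slots, n))
    idx0 <- (slots - 1L) * pitch + sample.int(min_separation %/% 2L + 1L, n, replace = TRUE)
    out <- lapply(seq_len(n), function(k) {
      i <- idx0[k]
      run <- sites[i:(i + n_sites - 1L), , drop = FALSE]
      if (length(unique(run$chrom)) != 1L) return(NULL)  # run spans a chromosome break
      data.frame(chrom = run$chrom[1L], start = min(run$pos),
                 end = max(run$pos) + 1L, fold_change = fold_change[k],
                 hyper_group = hyper_group[k], n_sites = n_sites,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    class(out) <- c("injected_dmr_truth", class(out))
    out
  })
}

#' Generate per-sample methylation profiles with injected differential regions
#'
#' Every LpnPI site gets a latent methylation fraction per sample: a shared
#' baseline plus Gaussian noise, clipped to `[0, 1]`. Inside each injected
#' region the hypermethylated group's expected fraction is
#' `baseline_mean * fold_change` while the other group stays at baseline, so
#' the expected group-mean ratio equals the requested fold change; outside
#' injected regions the two groups share the same expectation.
#'
#' @param genome A `genome_model`.
#' @param sample_sheet data.frame with `sample_id` and the grouping column.
#' @param injected `NULL` or a data.frame as returned by
#'   [sample_injected_dmrs()] (columns `chrom`, `start`, `end`, `fold_change`,
#'   `hyper_group`).
#' @param baseline_mean Baseline methylation fraction, in `(0, 1)`.
#' @param noise_sd Per-sample Gaussian noise on the fraction scale.
#' @param group_col Sample-sheet column naming the groups referenced by
#'   `hyper_group`.
#' @param seed Integer seed.
#' @return A `methylation_profile`: list with `sites`, `meth` (site x sample
#'   matrix of fractions), `sample_sheet`, and `truth` (the injected table plus
#'   a `site_idx` list-column of affected row indices in `sites`).
#' @export
generate_methylation_profiles <- function(genome, sample_sheet, injected = NULL,
                                          baseline_mean = 0.3, noise_sd = 0.05,
                                          group_col = "group", seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (baseline_mean <= 0 || baseline_mean >= 1) stopf("baseline_mean must be in (0, 1)")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  grp <- as.character(sample_sheet[[group_col]])
  if (length(unique(grp)) < 2L) stopf("sample sheet must contain two groups")
  sites <- genome_sites(genome)
  n <- nrow(sites)
  ids <- sample_sheet$sample_id
  mu <- matrix(baseline_mean, nrow = n, ncol = length(ids),
               dimnames = list(NULL, ids))
  truth <- NULL
  if (!is.null(injected) && nrow(injected) > 0L) {
    site_idx <- vector("list", nrow(injected))
    for (k in seq_len(nrow(injected))) {
      idx <- which(sites$chrom == injected$chrom[k] &
                     sites$pos >= injected$start[k] &
                     sites$pos < injected$end[k])
      if (length(idx) == 0L) {
        stopf("injected region %s:%d-%d contains no LpnPI site",
              injected$chrom[k], injected$start[k], injected$end[k])
      }
      fc <- injected$fold_change[k]
      if (fc < 1) stopf("injected fold change must be >= 1")
      hi <- baseline_mean * fc
      if (hi > 1) {
        stopf("fold change %.3g unattainable at baseline %.3g (fraction > 1)", fc, baseline_mean)
      }
      hyper <- grp == injected$hyper_group[k]
      if (!any(hyper)) stopf("hyper_group '%s' not present in column '%s'",
                             injected$hyper_group[k], group_col)
      mu[idx, hyper] <- hi
      site_idx[[k]] <- idx
    }
    truth <- injected
    truth$site_idx <- I(site_idx)
    truth$n_sites <- lengths(site_idx)
  }
  meth <- with_seed(seed, {
    if (noise_sd > 0) mu + matrix(stats::rnorm(length(mu), 0, noise_sd), nrow = n) else mu
  })
  meth[meth < 0] <- 0
  meth[meth > 1] <- 1
  structure(list(sites = sites, meth = meth, sample_sheet = sample_sheet,
                 truth = truth),
            class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("methylation_profile: %d sites x %d samples, %d injected region(s)\n",
              nrow(x$meth), ncol(x$meth),
              if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}
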