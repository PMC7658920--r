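#' Construct a site-by-sample count matrix
#'
#' The pipeline's central object: integer read counts per LpnPI site and
#' sample, with per-sample library sizes (column sums of filtered, assigned
#' reads).
#'
#' @param sites data.frame with `chrom` and `pos` (0-based), sorted by
#'   chromosome block then position.
#' @param counts Integer matrix, `nrow(sites)` rows; column names are sample
#'   ids.
#' @return A `site_count_matrix`: list with `sites`, `counts`, `lib_sizes`.
#' @export
site_count_matrix <- function(sites, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(sites)) stopf("counts and sites disagree on row count")
  if (is.null(colnames(counts))) stopf("counts must have sample ids as colnames")
  if (any(counts < 0)) stopf("counts must be non-negative")
  assert_sites_sorted(sites)
  structure(list(sites = sites,
                 counts = counts,
                 lib_sizes = colSums(counts)),
            class = "site_count_matrix")
}

#' Simulate per-site read counts directly from a methylation profile
#'
#' Shortcut that skips read-level simulation: the count at a site is Poisson
#' (or negative-binomial when `dispersion > 0`) with mean
#' `mean_depth * methylation fraction`. `dispersion` is the negative-binomial
#' overdispersion `phi` in `Var = mu + phi * mu^2`; the Poisson model is the
#' `phi -> 0` limit. Note the pooled chi-square test downstream assumes
#' Poisson/multinomial sampling; positive dispersion inflates its type-I error
#' (see the methods vignette).
#'
#' @param profile A `methylation_profile`.
#' @param mean_depth Expected reads at a fully methylated site (> 0).
#' @param dispersion Overdispersion `phi >= 0`; 0 gives Poisson counts.
#' @param seed Integer seed.
#' @return A `site_count_matrix`.
#' @export
simulate_site_counts <- function(profile, mean_depth = 30, dispersion = 0,
                                 seed = 1L) {
  stopifnot(inherits(profile, "methylation_profile"))
  if (mean_depth <= 0) stopf("mean_depth must be > 0")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  mu <- mean_depth * profile$meth
  counts <- with_seed(seed, {
    if (dispersion == 0) {
      stats::rpois(length(mu), lambda = mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
  })
  counts <- matrix(as.integer(counts), nrow = nrow(mu),
                   dimnames = dimnames(mu))
  site_count_matrix(profile$sites, counts)
}

#' Counts-per-million normalization
#'
#' Scales each sample column to counts per million by its library size (total
#' filtered assigned reads), the per-sample depth correction applied before
#' fold changes, Mann-Whitney comparisons and clustering. For a
#' `site_count_matrix` the normalized columns each sum to 1e6; for a
#' `region_count_matrix` the same per-sample factors (derived from the
#' site-level library sizes) are applied.
#'
#' @param x A `site_count_matrix` or `region_count_matrix`.
#' @return `x` with a `cpm` matrix added alongside the original integer
#'   counts.
#' @export
normalize_counts <- function(x) {
  UseMethod("normalize_counts")
}

#' @export
normalize_counts.site_count_matrix <- function(x) {
  zero <- x$lib_sizes == 0
  if (any(zero)) {
    stopf("zero library size for sample(s): %s",
          paste(names(x$lib_sizes)[zero], collapse = ", "))
  }
  x$cpm <- sweep(x$counts, 2L, x$lib_sizes, "/") * 1e6
  x
}

#' @export
normalize_counts.region_count_matrix <- function(x) {
  zero <- x$lib_sizes == 0
  if (any(zero)) {
    stopf("zero library size for sample(s): %s",
          paste(names(x$lib_sizes)[zero], collapse = ", "))
  }
  x$cpm <- sweep(x$counts, 2L, x$lib_sizes, "/") * 1e6
  x
}

#' @export
print.site_count_matrix <- function(x, ...) {
  cat(sprintf("site_count_matrix: %d sites x %d samples, median library %s\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$lib_sizes), big.mark = ",")))
  invisible(x)
}
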