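---
title: "Detecting differentially methylated regions from MeD-seq read counts"
author: "medseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differentially methylated regions from MeD-seq read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medseqr)
```

## The assay and its data

MeD-seq measures DNA methylation through the methylation-dependent
restriction enzyme *LpnPI*: the enzyme recognizes a CpG-containing site and,
when the CpG is methylated, cuts 16 bp downstream, releasing a 32-bp
fragment centered on the CpG. Fragments are sequenced as 50-bp single-end
reads. Because only methylated sites are cut, the read count at an *LpnPI*
site is a direct, single-CpG-resolution methylation signal, and a two-group
comparison of methylomes becomes a comparison of count profiles.

Two consequences of the chemistry shape the pipeline:

* A genuine *LpnPI* read carries its CpG at a characteristic distance from
  the read end. Reads are kept only if a known CpG site lies 13–17 bp
  (inclusive) from the 5′ **or** 3′ end; the canonical offset from the
  digestion geometry is 16, so the window is symmetric around it. We read
  "between 13 and 17" inclusively — the closed window keeps the canonical
  offset central.
* Each kept read is attributed to exactly one site. When two sites inside a
  read both satisfy the window (CpGs can sit 2 bp apart), the smaller
  genomic position wins; the tie-break is deterministic and recorded here
  because no published convention exists.

Coordinates are 0-based half-open everywhere inside the package; written
tables are 1-based inclusive, matching how positions are printed in reports.

## The statistical model

### The pooled chi-square test

For a feature (a single *LpnPI* site, a TSS window, a gene body or a CpG
island) with pooled read counts $a$ and $c$ in the two groups, whose pooled
library sizes are $N_1$ and $N_2$, we test homogeneity of proportions with
the 2×2 Pearson chi-square (1 df, no continuity correction):

$$\chi^2 = \frac{N\,(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)},
\qquad b = N_1 - a,\; d = N_2 - c.$$

Testing the count against the library remainder makes library-size
normalization implicit: the null hypothesis is equal *proportions* of the
two libraries falling on the feature. Counts are pooled across the samples
of a group rather than modeled per sample — this matches the assay's
original analysis and is cheap and powerful, but it is a *fixed-effect*
model: it assumes reads are multinomially sampled given the library sizes.
Two deviations from that assumption matter in practice:

* **Count overdispersion.** `simulate_site_counts()` offers negative
  binomial noise (`dispersion` $\phi$, variance $\mu + \phi\mu^2$). Any
  $\phi > 0$ inflates the pooled chi-square's type-I error (at
  $\phi = 0.05$, depth 30 and 14 + 15 samples the per-site variance is
  roughly 2.5× binomial). The generator's default is $\phi = 0$ (Poisson),
  under which the per-site p-values are uniform under the null — the
  calibration the test suite verifies.
* **Latent biological variability.** Per-sample methylation noise
  (`noise_sd`) acts like overdispersion after pooling, for the same reason.
  The default `noise_sd = 0.05` is a mild, realistic between-tumor
  variability; calibration checks therefore run at `noise_sd = 0`, and
  passing them demonstrates correctness of the test under its own sampling
  model, not robustness to biological replicate variance. Per-sample
  replicate models (e.g. beta-binomial regression) are out of scope by
  design.

### Region mode

`build_regions()` derives the three scored region classes from a gene table:
TSS windows span 1 kb on each side of the strand-aware TSS; gene bodies run
from 1 kb past the TSS to the TES; CpG islands are taken as provided. Genes
shorter than 2 kb contribute a TSS window only (logged). A site inside two
overlapping regions counts toward both — region classes are scored
independently, no exclusive assignment. `test_regions()` then applies the
pooled chi-square per region and keeps regions whose Bonferroni- or
BH-adjusted p-value falls below `alpha` (default 0.05, BH).

### Sliding-window mode

`sliding_window_dmrs()` tests every site, marks significant sites, and bins
maximal runs of significant sites on a chromosome into DMRs, splitting a run
wherever two *consecutive significant* sites lie more than `max_gap` bases
apart. Runs with fewer than `min_sites` sites are dropped; each DMR's
statistic is recomputed on its pooled counts and adjusted across DMRs.

Two numerical choices deserve justification:

* **Site-level correction before seeding** (`site_correction = "BH"`,
  default). Seeding on *uncorrected* p < 0.05 marks ~5 % of null sites.
  On a dense site index this floods the window: sporadic same-sign pairs of
  null sites survive the recomputed pooled test (which is anti-conservative
  after selection), and null neighbors chained onto true runs dilute their
  fold changes. It is also incompatible with genome scale — at ~28 M CpG
  sites, uncorrected seeding would nominate over a million sites, orders of
  magnitude more than any reported DMR count. BH-correcting the per-site
  p-values before seeding restores both calibration (under the global null
  the probability of seeding anything is about `site_alpha`) and fold-change
  accuracy. The uncorrected variant remains available via
  `site_correction = "none"`.
* **`max_gap` scales with site density.** The gap parameter exists to
  bridge assay gaps *relative to typical inter-site spacing*. The default
  1000 bp suits human CpG spacing (~100 bp median genome-wide). The
  synthetic genomes used in the tests are ~5× denser (CpG rate 0.05, ~20 bp
  median spacing), so simulations use `max_gap = 100` — about five median
  spacings, the same relative reach. Using 1000 bp at that density would
  merge independently injected regions placed ~800 bp apart.

### Fold change, status and filtering

`compute_fold_change()` works on per-sample CPM values summed over the DMR's
sites, with a raw-count pseudocount (default 0.5) added before scaling. The
fold change is the larger group mean over the smaller, so it is always
≥ 1; the group with the larger mean is marked hypermethylated (`+`), the
other hypomethylated (`-`), and exact ties give `=` on both sides.
`filter_dmrs()` applies the conventional fold-change ≥ 1.5 cut and removes
records on canonical sex chromosomes (`X`, `Y`, `chrX`, `chrY` exactly —
alternate contigs with embedded chromosome strings are retained, since alt
contigs legitimately appear in reported DMR tables).

A record with a *missing* fold change — printed tables occasionally omit
one — behaves as if its fold change were `na_fold_change` (default 1.5):
its presence in a table whose inclusion rule is "fold change ≥ 1.5"
certifies that bound but nothing stricter, so such records pass thresholds
up to 1.5 and fail stricter ones. Records whose printed start exceeds their
end are ingested as-is, flagged `valid_interval = FALSE`, skipped by
interval arithmetic, and never silently corrected.

### Downstream statistics

`mannwhitney_u()` implements the two-sided Mann–Whitney U test with the
smaller-U convention: exact doubled-tail p-values for small tie-free samples
(`min(n, m) ≤ 8` in auto mode), otherwise the tie-corrected normal
approximation without continuity correction (the convention of the
statistics package used in the original analysis). `dmr_group_test()`
applies it per DMR to the per-sample CPM values; `expression_validation()`
applies it per probe of each requested gene, reporting pooled medians and
IQRs one row per probe (genes are often covered by several probes, and the
pooled single summary column mirrors how such tables are printed).

`cluster_samples()` reproduces the supervised-clustering construction: DMRs
are selected by a supervised contrast, then *all* samples are clustered on
those DMRs — selection is supervised, the clustering itself unsupervised.
Values are log2(CPM + 1) transformed and z-scored per DMR (zero-variance
DMRs dropped), distances are Euclidean (1 − Pearson available), linkage is
average by default; none of these were specified in the original analysis,
so the simplest standard choices are used and exposed. The 2-cluster cut is
summarized against cohort covariates as cluster purity plus, for binary
covariates, the minimum misplaced-sample count over label matchings.
`size_based_dmrs()` builds the size-extreme contrast (≤ 34 mm vs > 87 mm by
default — the cohort's printed quartile bounds) and delegates to the DMR
caller.

## The synthetic-data generator

The generator emulates the study conditions so that every pipeline stage is
testable with ground truth:

* **Genome** — random sequence with an exact CG-dinucleotide rate
  (`cpg_rate`, default 0.05): a CG-free background with
  `round(rate × length)` CG blocks stamped on a non-overlapping grid.
  Non-overlapping genes ≥ 2 kb (so both region classes are non-empty) and
  CpG islands are placed uniformly. Any CpG is an *LpnPI* site.
* **Cohort** — 14 S45F + 15 T41A samples; sex 19 F / 10 M; tumor site
  20/6/3 extra-abdominal / abdominal wall / intra-abdominal; size lognormal
  with median 55 mm and IQR 34–87 mm with 3 missing values; age lognormal
  with median 36 and IQR 26–47 years — the published cohort summary.
* **Methylation** — a shared baseline fraction (default 0.3, a realistic
  genome-wide average given that scored sites mix methylated and
  unmethylated compartments) plus Gaussian per-sample noise (default 0.05),
  clipped to [0, 1]. Injected DMRs raise the hypermethylated group to
  `baseline × fold_change` over a run of consecutive sites; requested fold
  changes default to the 1.5–2.68 range seen in reported tables. Injection
  in recovery studies is *balanced* across groups (25 regions
  hypermethylated in each), because one-sided injection of 50 regions
  inflates one group's library by ~8 % and biases every null site — the
  compositional effect familiar from expression analysis.
* **Digestion and reads** — each site is emitted with probability equal to
  its methylation fraction as a `[c−16, c+16)` fragment (length exactly 32,
  C at offset 16); each fragment yields one 50-nt read whose site offset is
  drawn from `offset_jitter` (default [13, 17]; widen it to exercise filter
  failures), padded with a fixed adapter. A truth table links every read to
  its site and offset.
* **Counts** — `simulate_site_counts()` shortcuts read simulation with
  Poisson (default) or negative binomial counts of mean
  `mean_depth × methylation`.

What the generator does **not** emulate: FFPE artifacts (deamination,
fragmentation), bisulfite chemistry, base-call errors, adapter errors,
mappability, or the real genome's CpG clustering into islands and deserts.
Passing the recovery and calibration suites therefore demonstrates the
pipeline's correctness under its own sampling model, not performance on
archival clinical libraries.

## Determinism and problem sizes

Every stochastic operation takes an explicit integer seed and restores the
caller's RNG state; identical seeds and parameters give byte-identical
outputs, including written files (which carry a header comment with the
package version, seed and a config hash). The simulation studies in the
test suite use 100-kb genomes (~5,000 sites) with 29-sample cohorts: null
calibration over 20 seeds, recovery of 50 injected two-fold 8-site DMRs per
seed over 20 seeds, and a 6 + 6 size-extreme clustering contrast — sizes
chosen so the suite gives stable statistical verdicts while running in
seconds per seed.

## Known limitations

* The pooled chi-square ignores between-sample variance; with real tumor
  heterogeneity its p-values are optimistic. The per-DMR Mann–Whitney test,
  which does respect per-sample variation, is the more conservative
  companion readout.
* Fold changes of sliding-window DMRs are computed over the called interval;
  chained null neighbors (rarer with corrected seeding, but possible) dilute
  them toward 1.
* The sex-chromosome filter matches canonical names only; an alternate
  contig of X would be retained.
* Region annotation does not clip TSS windows at neighboring genes, and a
  DMR overlapping both a TSS window and a gene body is labeled `TSS`.
* Alignment is out of scope: real-data mode ingests mapped positions;
  synthetic mode uses exact placement.

## A minimal end-to-end run

```{r example, eval = FALSE}
config <- medseq_config(seed = 11, chrom_lengths = c(chr1 = 60000L),
                        n_injected = 4L, injected_fold_change = 2)
res <- run_pipeline(config)
res$dmrs[, c("chrom", "start", "end", "n_sites", "q", "fold_change")]
res$clustering$purity
```
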