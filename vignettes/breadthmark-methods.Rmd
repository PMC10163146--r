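---
title: "Methods: spike-in normalisation, promoter-state classification and peak-breadth stratification"
author: "breadthmark authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in normalisation, promoter-state classification and peak-breadth stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`breadthmark` implements the chromatin–transcriptome integration analyses
used to study the maintenance role of promoter H3K4 methylation in
terminally differentiated cells, such as pancreatic beta cells with a
conditional knockout of the COMPASS core subunit DPY30. The package takes
peak calls, binned signal tracks, spike-in read summaries and count
matrices as inputs; read alignment, peak calling, trajectory inference and
regulon inference are upstream concerns and out of scope. All genomic
intervals are handled in a single convention — 0-based, half-open,
BED-style — with 1-based formats (GTF) converted at the I/O boundary, so
no off-by-one ambiguity can travel between modules.

The analysis stages are:

1. **Spike-in (ChIP-Rx style) normalisation.** Every library receives a
   fixed amount of foreign-cell chromatin (or a fixed spike-cell
   proportion for RNA), so spike reads measure per-cell yield. Scale
   factors use the reference-to-minimum convention,
   $f_j = \min_k s_k / s_j$ for spike counts $s_j$: the shallowest library
   keeps factor 1 and all others are scaled *down*, which never inflates
   noise. Equal-total ("CPM-style") scaling is the contrast case: it
   forces every library to the same mass and therefore erases exactly the
   global signal differences this design is built to detect.
2. **Promoter chromatin-state classification.** Using knockout peak
   calls, a gene is group *i* if any H3K4me3 peak shares at least one
   base with TSS ± 1 kb, group *ii* if none does but an H3K4me1 peak
   does, and group *iii* otherwise. "Retained at least some enrichment"
   is operationalised as a ≥ 1 bp overlap between a peak call and the TSS
   window; the window half-width (1 kb) matches the TSS fold-change
   operators. Merging replicate peak calls is the caller's job: one peak
   file per condition is consumed as-is, and overlapping peaks are never
   merged on read so breadth statistics see caller output unchanged.
3. **Signal summaries.** Metagene TSS profiles average strand-oriented
   windows (minus-strand windows reversed); genome-bin and TSS-window
   fold changes are $\log_2((b + c_0)/(a + c_0))$ with a pseudocount
   $c_0 = 1$ signal unit per window, which pins empty regions at exactly
   0 rather than ±∞. The genome-bin size defaults to 10 kb and signal
   tracks are dense fixed-bin arrays (default 50 bp — a choice, since
   browser-track bin widths are rarely reported; exposed in the
   configuration) so these operators are array slices.
4. **Breadth stratification.** Peaks are ranked by breadth (stable sort
   by breadth, chromosome, start) and cut into $Q = 20$ equal-count
   quantiles — each holding 5% of peaks, sizes differing by at most one —
   rather than equal-breadth bins, so quantile membership is a
   permutation-invariant function of the peak multiset. Gene sets are
   tested per quantile with one-sided Fisher's exact tests (upper
   hypergeometric tail; depletion simply shows as $p \to 1$), BH-corrected
   across the $Q$ tests, after intersecting the set with the
   promoter-assigned universe (dropped genes are messaged). A gene's
   promoter peak is the maximal-overlap peak in TSS ± 1 kb, ties broken by
   breadth, then leftmost start, then peak id.
5. **Cross-condition peak matching.** Peak callers split and merge peaks
   between conditions — precisely the phenomenon under study — so
   matching uses connected components of the ≥ 1 bp overlap graph over the
   combined peak set, comparing the union span of each side:
   $\log_2(\mathrm{span}_b / \mathrm{span}_a)$. A breadth change is
   flagged as substantial at $|\log_2| \ge 1$ by default; this threshold
   is a configuration knob reported in output metadata, since no
   community-standard criterion exists.
6. **Single-cell consistency.** Transcriptional entropy is the Shannon
   entropy (bits) of a cell's gene-proportion vector after downsampling
   every cell, without replacement, to a common depth; raw-depth entropy
   confounds sequencing depth with biology, and the common depth makes the
   cluster contrast interpretable. Zero proportions contribute 0
   ($0 \log 0 = 0$) and all genes are retained, so entropy is invariant to
   gene order and padding and bounded by $\log_2 G$. Fano factors are
   variance/mean of *raw* counts within cluster (sample variance, $n-1$):
   the standard noise estimator, intentionally free of normalisation
   choices. The cluster-2/cluster-1 ratio uses a small floor (default
   0.01) before the log.
7. **Enrichment machinery.** Running enrichment uses the unweighted
   (classic Kolmogorov–Smirnov) walk, $+1/|S|$ on set members and
   $-1/(N-|S|)$ elsewhere, because its extremes are exactly ±1 — which the
   test suite uses as closed-form oracles. The permutation null draws
   random same-size gene sets (not ranking permutations); NES divides the
   enrichment score by the mean |null score| of matching sign, and the
   permutation p-value is floored at $1/(n_\mathrm{perm}+1)$ so no zero
   p-values are emitted. The rank–rank hypergeometric overlap map ranks
   both DE tables by signed significance, $-\log_{10}(p)\cdot
   \mathrm{sign}(\log_2 FC)$ with ties broken by fold change then gene id,
   and scores each rank-threshold pair with the upper hypergeometric tail
   on the intersected universe; cells whose prefix ends represent
   concordant directions are positive, discordant cells negative.

Statistical conventions throughout: Wilcoxon rank-sum tests for
distribution shifts (via `stats::wilcox.test`: exact for small untied
samples, normal approximation with tie correction otherwise), Spearman's
coefficient as the headline correlation with Pearson's r reported
alongside (the two appear interchangeably in this literature, so both are
returned), and Benjamini–Hochberg correction wherever families of tests
are reported. Group comparisons with fewer than two members return
missing p-values, never 1.

# The DE stand-in

Differential expression between two conditions is provided as deliberate
plumbing, not a contribution: per-gene $\log_2$ fold change of
spike-normalised means (pseudocount 1), a two-sample t-test on
$\log_2(\mathrm{norm} + 1)$ values, BH adjustment, and the twofold /
adjusted-$p \le 0.01$ status rule. Users with a dedicated DE engine
(DESeq2-class Wald tests) can feed its table anywhere a `DETable` is
consumed.

The test pools the group variances by default. With the design's two to
three replicates per condition, the Welch–Satterthwaite degrees of
freedom routinely collapse towards 2, which caps attainable p-values near
$10^{-3}$; after BH correction across thousands of genes this leaves the
caller essentially powerless at *any* effect size — measured sensitivity
plateaus around 0.8 even for eightfold changes. The pooled test keeps the
full $n_1 + n_2 - 2$ degrees of freedom, is appropriate here because the
two groups' count variances are exchangeable under the generative design,
and restores calibrated power (no calls on null data; > 0.9 sensitivity
for eightfold changes at well-measured genes). `pool_variance = FALSE`
selects Welch's test for designs with more replicates.

# The synthetic-data generator

The generator (`sim_config()` and the `simulate_*` functions) defines the
study conditions under which every guarantee is tested. It emulates the
*structure* of the emulated experiment, not its scale:

* **Genome**: 2,000 evenly spaced genes (30 kb apart, alternating
  strands, two chromosomes), every TSS at its slot centre. Real genomes
  have clustered promoters and overlapping transcripts; the even spacing
  isolates promoter-window logic from annotation ambiguity.
* **ChIP signal**: every gene gets a promoter H3K4me3 peak with breadth
  from a two-component log-normal mixture — a typical component
  (median ≈ 1.5 kb) plus a broad tail (5% of peaks, median ≈ 8 kb, capped
  at 21 kb, the scale of the broadest promoter domains reported for these
  cells). Knockout signal is wild-type times `global_depletion`
  (default 0.5); on top, 15% of genes lose the H3K4me3 peak but keep
  H3K4me1 (group ii) and 1% lose both (group iii), proportions chosen to
  mirror the reported relative group sizes. The *realised* noise-free
  KO/WT signal-mass ratio (slightly below the depletion factor, because
  group-ii/iii losses remove mass too) is recorded as truth and is the
  reference for recovery checks. Observed tracks carry per-library
  log-normal depth factors (SD 0.1) and per-bin multiplicative noise
  (SD 0.1); spike counts share the library depth factor with 2%
  residual noise, i.e. the equal-spike-in design.
* **Bulk expression**: negative-binomial counts, 3 replicates per
  condition, baseline means log-normal around 50. Planted fractions
  default to 4.3% down and 1.3% up (the reported proportions of
  dysregulated genes), with $|\log_2 FC| \sim N(1.5, 0.3)$. Dispersion is
  0.01, representing the low biological variability of FACS-purified,
  genotype-matched replicates; this is also the regime in which the
  stand-in's prescribed calibration (silent null, > 0.9 sensitivity at
  eightfold) is coherent with a 3 + 3 t-test. Down-regulated genes are
  placed, with probability `extreme_coupling` (default 0.8), at genes
  whose promoter peak sits in the narrowest or broadest breadth quantile
  — placement at the *truth* level, using the same ranking rule as the
  downstream quantile operator, so the U-shaped enrichment profile is an
  emergent property of the pipeline rather than a post-hoc filter.
  Planting is restricted to genes with baseline mean ≥ `de_min_mean`
  (default 10), since effects below the detection floor are not
  informative about recovery.
* **Single cells**: two clusters of 300 cells. Cluster-1 pseudotime is
  concentrated near 0 (Beta(1.2, 12)); cluster 2 spreads towards 1
  (Beta(2.5, 1.5)). Cluster-2 proportion vectors are flattened with
  exponent $1/(1 + \text{entropy\_shift} \cdot t)$ — raising entropy along
  pseudotime — and per-gene dispersion is inflated threefold, optionally
  increasing with promoter breadth (`fano_breadth_coupling`, default 0.3,
  interpolating the inflation geometrically along the breadth rank).
  Counts are gamma-multinomial at log-normal depth (median 5,000).
  Pseudotime is generated, not inferred: trajectory inference is out of
  scope, and generating it isolates the entropy statistic from it.

Everything is a pure function of the configuration: each stage derives
its seed from the master seed, and rerunning a fixed configuration
reproduces every output byte-for-byte (the end-to-end suite asserts
this). What passing tests on this generator do *not* show: robustness to
promoter-dense annotations, to peak-caller artefacts (the planted peaks
are noise-free calls), to batch effects or ambient contamination in the
single-cell arm, or to DE misspecification beyond the NB family.

# Numerical choices and degenerate inputs

* Fisher tails come from the hypergeometric CDF; the suite checks them
  against exhaustive binomial-coefficient enumeration to $10^{-12}$ for
  all tables with total ≤ 30 and enrichment universes ≤ 300.
* Degenerate Fisher margins give $p = 1$; a $0/0$ odds ratio is missing.
* Metagene windows are snapped to the track grid and zero-padded at
  chromosome bounds (padded genes still count in the average).
* Quantile assignment under tied breadths is fixed by (chromosome,
  start), so reruns are byte-identical; the first $N \bmod Q$ quantiles
  take the extra peak when $Q \nmid N$.
* Entropy downsampling uses exact without-replacement sampling; cells
  below the target depth are dropped with a message, never silently.
* Breadth draws below 1 bp or above the cap are resampled (messaged).
* All permutation p-values are floored at $1/(n_\mathrm{perm}+1)$;
  $-\log_{10} p$ grids are floored at the double-precision minimum.

# Problem sizes

The shipped test-suite and acceptance runs use the generator defaults
(2,000 genes, 50 bp bins over a ~60 Mb genome, 3 + 3 bulk replicates,
2 × 300 cells) for end-to-end checks, and reduced sizes (400–1,000 genes,
2 × 120–200 cells, entropy depth 1,000) where a property is being checked
across many seeds; each such size is stated at the call site. These
choices keep the whole suite reproducible on a laptop while leaving every
statistical contrast far from its decision boundary.

# Interfaces

The exported functions are the package's interface, composed end-to-end
by `run_all()` on a single `pipeline_config()` (YAML-loadable via
`pipeline_config_from_yaml()`), which writes the per-stage tables
(`genes.tsv`, `peaks_*.bed`, `spike_counts.tsv`, `bulk_counts.tsv`,
`cells.mtx` + metadata, `de_table.tsv`, `groups.tsv`, `quantiles.tsv`,
enrichment and consistency tables) plus a `report.json` scoring every
stage against the planted truth. Every table carries the configuration
hash, so mixing tables from different runs is detectable; stages are
skipped only by explicit configuration, never inferred from partial
outputs.

# Known limitations

* The DE stand-in shares no information across genes; it is calibrated,
  not powerful, and is not a substitute for a dedicated DE engine at
  realistic dispersions.
* Promoter assignment considers TSS-proximal peaks only; distal enhancer
  methylation is not modelled.
* Peak matching by union span is insensitive to internal structure: a
  component that both splits and shifts is summarised by its span change
  only.
* The entropy estimator depends on the chosen common depth; contrasts are
  comparable only within one depth.
* Spike normalisation assumes the spike material is constant per cell
  across libraries; degradation or mixing errors propagate directly into
  the scale factors.
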