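---
title: "Methods: symmetric-null probe statistics and promoter co-occupancy"
author: "chipnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symmetric-null probe statistics and promoter co-occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipnet)
```

## The problem

Two-colour ChIP-chip on a *non-tiling* promoter array compares, probe by
probe, the immunoprecipitated chromatin fraction (IP, intensity $y$)
against total input chromatin (intensity $x$).  Because probes sample
promoters sparsely, sliding-window peak callers built for tiling designs
do not apply: the decision has to be made per probe, and gene-level
calls are assembled from the probes in each promoter window.  chipnet
implements that per-probe statistic, the replicate and gene-level
calling rules, and the downstream analyses a factor-occupancy study
needs: co-occupancy matrices, TSS binding profiles, integration with
differential mRNA/miRNA expression, simplified motif enrichment, and
$2^{-\Delta\Delta C_t}$ qPCR quantification.

All stages are exercised against a synthetic-data generator with
planted ground truth, so the whole pipeline is testable without any
microarray download.

## The probe statistic

Each probe yields a normalized pair $(x, y)$ of log2 intensities
(`normalize_pairs()`: per-channel log2 + median centring, then the
global median of $d = y - x$ is set to zero).  The single modelling
assumption is **null symmetry**: probes not bound by the factor scatter
symmetrically around the identity axis $y = x$.  Enrichment can only
push $y$ up, so the probes *below* the axis are a reflected sample of
the null distribution of deviations.

`estimate_null()` turns that reflected sample into an
intensity-dependent scale model: below-axis probes are split into
equal-count bins of the input intensity $x$, each bin contributes a
robust scale $s_\mathrm{bin} = \mathrm{median}(|d|)/0.6745$ (the
normal-consistency constant), and a cubic smoothing spline with
GCV-chosen smoothness is fitted through the bin scales, giving $s(x)$
clamped at the ends of the observed range.  The normalized distance of
any probe from the axis is then $z = d / s(x)$, and the threshold curve
at level $\alpha$ is $y = x + z^*_\alpha\, s(x)$ — the spline curve
that separates background from positive probes in the scatter plot.

Two details are deliberate choices:

* **Covariate.** The scale is modelled as a function of the input
  intensity $x$, not of the average intensity $A = (x+y)/2$ (which is
  also computed and reported).  $A$ contains half of the very deviation
  being normalized; with a steep intensity-dependent spread this smears
  the scale estimate asymmetrically — above-axis probes get evaluated
  at slightly higher intensity, hence smaller scale and inflated $z$ —
  and measurably mis-calibrates the tail (fraction of null probes at
  $p \le 0.01$ drifts to $\approx 0.017$).  Conditioning on $x$, which
  is noise-free with respect to $d$, restores calibration; it is also
  the axis the threshold curve is actually drawn over in an input/IP
  scatter plot.
* **Distance.** $d = y - x$ is used rather than the perpendicular
  distance $(y-x)/\sqrt{2}$; the two differ by a constant factor that
  the scale $s(x)$ absorbs.

### P-values

Two one-sided p-values are offered (`probe_pvalues()`):

* `empirical` (default): the survival function of the symmetric null
  reconstructed from the reflected sample.  For $z > 0$,
  $p = \tfrac{1}{2}\,(1 + \#\{z_j^{\mathrm{null}} \ge z\})/(1 + N)$,
  with the mirrored complement for $z \le 0$; ties count as $\ge$
  (conservative), probes on or below the axis get $p \ge 0.5$.  The
  factor $\tfrac12$ makes the p-value one-sided: the reflected sample
  estimates the distribution of $|Z|$, and under symmetry
  $P(Z \ge z) = \tfrac12 P(|Z| \ge z)$ for $z > 0$.  Written without
  it, the statistic would be a two-sided tail and a pure-null array
  would yield only half the nominal rate below any threshold — the
  one-sided form is what makes the p-values uniform on $(0,1]$, which
  the test suite verifies by simulation (KS test, and tail rates at
  $\alpha \in \{0.05, 0.01, 0.001\}$).
* `gaussian`: the upper standard-normal tail of $z$, for when p-values
  beyond the empirical resolution ($\approx 0.5/N_\mathrm{null}$) are
  needed.  It adds a normality assumption the empirical method does not
  make.

### Replicate and gene rules

Technical replicates are combined per probe (`combine_replicates()`)
with the fixed conjunction rule

$$ p_1 p_2 < 10^{-3} \;\wedge\; p_1 < 10^{-2} \;\wedge\; p_2 < 10^{-2}, $$

and the geometric mean $\sqrt{p_1 p_2}$ is recorded for every probe.
The constants are read as $10^{-3}$/$10^{-2}$; the literal
scientific-notation reading (10e-3 = 0.01, 10e-2 = 0.1) is available
via `literal = TRUE` for sensitivity analyses.  A gene's best probe is
the one minimising the geometric mean (ties: smaller $p_1$, then
lexicographic probe id); the gene is positive iff its best probe passes
the rule, and `strict = TRUE` additionally demands geometric mean
$\le 10^{-3}$ — the two published formulations of the cut-off, kept as
explicit modes because they differ (product $<10^{-3}$ vs product
$\le 10^{-6}$).  No multiple-testing correction enters the calling
path; a Benjamini–Hochberg column is emitted for information only.

Promoter windows default to $\pm 4$ kb around the TSS (8 kb total),
half-open in genomic coordinates, with distances signed in the
direction of transcription (upstream negative).

## Downstream stages

* **Co-occupancy** (`build_matrix()`, `cluster_rows()`,
  `extract_groups()`, `pairwise_overlap()`, `compare_timepoints()`):
  rows are genes positive for at least one factor, cells
  $-\log_{10}$(best geometric mean) or 0.  Clustering uses Euclidean
  distance on scores capped at 10 (so a handful of extreme p-values
  cannot dominate) with average linkage; metric, linkage and cap are
  arguments since the original choice is not documented anywhere.
  Exact combination groups partition the positive universe (asserted in
  tests).  Pairwise overlap is tested per factor pair on a 2×2 table
  over the whole array (not just positives, which would bias the
  correlation), reporting the phi coefficient, the uncorrected
  chi-square, and the two-sided Fisher exact p — Fisher because small
  groups are common.
* **TSS profiles** (`tss_profile()`, `peak_summary()`): per 250-bp
  half-open bin of signed TSS distance, the ratio of positive to total
  probes.  Bins are stored linearly; any log scaling is left to
  plotting because log-binning a signed axis is ill-defined at 0.
  Modal-bin ties break toward the TSS, then to the lower bin.
* **Expression integration** (`total_gene_signal()`, `qc_regression()`,
  `differential()`, `integrate_chip_expression()`, `intersect_mirna()`,
  `pathway_filter()`): total gene signal is (sum of probe signals) ×
  probe count, exactly as defined for the miRNA arrays; replicate QC
  regresses natural-log TGS between samples over features above 10×
  background and reports the residual SD as RMSD.  Differential calling
  is a Welch t-test on log2 signals plus a fold-change gate (the
  original software's internal test is undocumented; Welch + fold
  change is the minimal documented equivalent, with BH alongside).  The
  pathway filter keeps a pathway iff $\ge 3$ miRNAs reach
  $-\ln p > 3$; the "union" row of the kept-matrix is the column-wise
  minimum p across miRNAs, a common merged-miRNA convention, flagged
  here as an interpretation.
* **Motif enrichment** (`kmer_enrichment()`, `make_pwm()`,
  `pwm_scan()`, `motif_chisq()`): full de novo discovery and
  motif-database comparison are deliberately replaced by canonical
  k-mer enumeration (k in 7–18, reverse-complement collapsed, Yates
  2×2 chi-square) and user-supplied PWMs (log2-odds, pseudocount 0.5,
  0-order background from the negative set).  What is preserved
  faithfully is the *testing* machinery: the chi-square homogeneity
  test of score distributions between positive and negative probes,
  on pooled quantile bins merged until expected counts reach 5
  (df = K−1).  Quantile binning makes the test invariant to monotone
  transforms of the score.  The negative set defaults to non-positive
  probes from the same array.  Soft-masked (lower-case) positions never
  contribute k-mers or PWM windows.
* **qPCR** (`chip_fold_enrichment()`, `relative_expression()`): plain
  $2^{-\Delta\Delta C_t}$ without amplification-efficiency correction.
  ChIP validation is called positive at $\ge 3$-fold over IgG (the
  input terms cancel algebraically and are accepted only as a sanity
  control); expression is quantified against a reference amplicon and a
  calibrator condition, with a two-sided t-test on replicate
  $\Delta C_t$ values — the approximately normal scale — rather than on
  folds.

## The synthetic-data generator

`make_annotation()` tiles `floor(window/spacing) + 1` probes across
$\pm$ window/2 of each TSS (defaults 8 kb, 600 bp spacing → 14 probes,
the density of a 244k-probe array covering ~17,000 promoters).
`simulate_chip()` draws a base log2 abundance per probe
($N(10, 1.5^2)$), adds symmetric noise with intensity-dependent spread
$\sigma(x) = 0.2 + 0.6\,e^{-(x - x_0)/2}$ (dim probes noisier, forcing
the spline stage to matter; optionally scaled-t with 5 df for
heavy-tailed checks), and adds to bound genes' probes an IP-channel
shift of $\mathrm{effect} \times \sigma \times K(\cdot)$, where $K$ is
a triangular kernel of half-width 1 kb around the gene's binding
centre.  Defaults plant 5% bound genes at effect 6 — the operating
point at which the calling rules are expected to recover truth at
sensitivity $\ge 0.9$ with empirical FDR $\le 0.05$, which the tests
verify at full array scale over five seeds.  Binding centres are drawn
$N(-250, 300)$ bp for promoter-proximal factors and $N(+1500, 700)$ bp
for factors binding inside the transcribed region, so the TSS-profile
stage has a planted qualitative contrast (~1.75 kb between modal
bins).  The kernel half-width of 1 kb reflects the fragment sizes of a
sonicated ChIP and guarantees, with 600 bp probe spacing, at least one
probe at kernel weight $\ge 0.7$ for every bound gene.

What the generator does **not** emulate: dye bias, print-tip and
spatial artefacts, whole-genome-amplification distortions, probe
sequence effects, or the raw-intensity distributions of any real
feature-extraction software (those are undocumented for the arrays in
question; the generator's parameters are chosen for statistical
plausibility).  Passing tests therefore demonstrate the correctness
and calibration of the *statistics* under the stated assumptions, not
robustness to every real-array artefact.  The heavy-tailed noise mode
exists precisely to probe the gap between "symmetric" (assumed) and
"Gaussian" (not assumed).

## Numerical and design notes

* Equal-count intensity bins (default 20) need at least 10 reflected
  probes each, or `estimate_null()` aborts advising fewer bins.
* The fitted scale is floored at a small positive value and clamped to
  the observed intensity range, so $s(x) > 0$ everywhere and
  extrapolation is flat.
* Empirical threshold curves use the order statistic of the reflected
  sample at which the empirical p-value first drops below $\alpha$;
  classification by curve and by p-value agree exactly, including ties
  (tested).  `alpha = 0.5` degenerates to the identity axis.
* Degenerate inputs are defined, not crashed on: genes without probes
  are emitted negative with NA fields; zero-variance expression
  features give $p = 1$ (equal means) or 0; all-identical motif scores
  give $p = 1$; empty positive sets yield flagged NA summaries.
* Coordinates are 0-based half-open throughout; BED export/import
  validates this and reports offending line numbers.
* Problem sizes in the tests and analysis scripts (e.g. 4,000-promoter
  arrays in the workflow, 17,000 at full scale in the recovery checks,
  112k probes for calibration) are chosen so every statistical check
  retains its power while the whole suite runs in about a minute.

## Analysis workflow

The `analysis/` directory holds numbered drivers
(`01_simulate.R` … `08_qpcr_validation.R`) that replay the full study
on the synthetic design — simulation, probe statistics, gene calls,
co-occupancy with planted combination structure (a 45-gene six-factor
core and a 70% PRC/ERR1 share), TSS profiles, expression integration,
motif enrichment, qPCR validation — writing their tables under
`results/`.  Each script is self-contained and deterministic;
`scripts/acceptance.R` recomputes the headline quantities from scratch
and writes them as JSON.

## Known limitations

* The per-probe statistic ignores spatial correlation between
  neighbouring probes of one promoter; it is a feature of the
  non-tiling design, not a bug, but it leaves power on the table for
  tiling data (out of scope).
* The empirical p-value resolution is $0.5/(1+N_\mathrm{null})$;
  product-rule thresholds far below that need the gaussian method.
* `extract_context()` and the motif stage operate on supplied sequence
  strings; no genome assembly handling is included.
* The pathway filter consumes a supplied miRNA × pathway p-value
  matrix; target prediction and pathway annotation databases are
  external by design.
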