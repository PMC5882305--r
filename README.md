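# chipnet

Statistical calling and integration for two-colour ChIP-chip on
**non-tiling promoter arrays**, with a fully synthetic, planted-truth
test bed.

## The problem

ChIP-chip hybridizes an immunoprecipitated chromatin fraction (IP,
intensity *y*) and total input chromatin (intensity *x*) to the same
probe array. On promoter arrays the probes sample each promoter
sparsely (~14 probes across 8 kb around the TSS), so tiling-array peak
callers do not apply: each probe needs its own test, and gene calls are
assembled from the probes in the promoter window. chipnet is written
for analysts studying transcription-factor/coactivator occupancy
networks — which factors bind which promoters, where relative to the
TSS, in which combinations, and how that aligns with differential
mRNA/miRNA expression and qPCR validation.

## The statistic

After per-channel log2 normalization and centring of d = y − x, the
core assumption is **null symmetry**: unbound probes scatter
symmetrically around the identity axis y = x. Enrichment only pushes
y up, so probes *below* the axis form a reflected sample of the null.
chipnet:

1. fits an intensity-dependent robust scale s(x) — per equal-count
   intensity bin, median(|d|)/0.6745 of the below-axis probes, smoothed
   by a cubic spline (GCV);
2. scores every probe by its normalized distance z = d / s(x) and
   assigns a one-sided p-value, either empirical (survival function of
   the symmetric null reconstructed from the reflected sample; default)
   or Gaussian (upper-normal tail of z);
3. combines two technical replicates per probe with the fixed rule
   p₁·p₂ < 10⁻³ ∧ p₁ < 10⁻² ∧ p₂ < 10⁻², recording the geometric mean
   √(p₁p₂);
4. calls a gene positive when its best promoter probe (minimal
   geometric mean) passes the rule.

The threshold spline curve y = x + z*·s(x) at any level α is exported
for plotting, and classification by curve equals classification by
p-value exactly.

Downstream modules build the genes × factors occupancy matrix
(−log₁₀ best geometric mean), cluster it, extract exact
factor-combination groups, test pairwise co-occupancy (phi, chi-square,
Fisher), profile positive-probe distances from the TSS, integrate with
differential expression (Welch t + fold change on total gene signals,
10× background QC, −ln p > 3 pathway filtering), run simplified k-mer /
PWM motif enrichment with a chi-square homogeneity test of score
distributions, and compute 2^−ΔΔCt qPCR enrichment (≥3-fold vs IgG
rule) and relative expression.

Because real deposited array data are not required, a synthetic-data
module (`make_annotation`, `make_truth`, `simulate_chip`,
`simulate_expression`, `simulate_qpcr`, `simulate_sequences`) generates
every input with planted ground truth, and the test suite verifies
calibration and parameter recovery against that truth.

## Worked example

Simulate a 2,000-promoter array with 5% of genes bound by one factor at
effect size 6, run the full calling path, and compare with the planted
truth:

```r
library(chipnet)

ann   <- make_annotation(n_genes = 2000, window_bp = 8000,
                         probe_spacing_bp = 600, seed = 1)
truth <- make_truth(ann, factors = "PRC", bound_fraction = 0.05,
                    effect = 6, seed = 2)
sim   <- simulate_chip(ann, truth, n_replicates = 2, seed = 3)

pv <- lapply(sim$replicates, function(r) {
  pairs <- normalize_pairs(r)
  model <- estimate_null(pairs)          # reflected-null scale spline
  probe_pvalues(pairs, model, "empirical")
})
comb  <- combine_replicates(pv[[1]], pv[[2]])
asn   <- assign_probes(ann, ann$probes)
calls <- call_genes(asn, comb, genes = ann$genes$gene_id)

calls[positive == TRUE][order(best_gm)][1:3]
#>    gene_id best_probe_id        pVal1        pVal2      best_gm tss_distance positive         bh
#> 1:  g00008    g00008_p08 3.571173e-05 3.571173e-05 3.571173e-05          200     TRUE 0.00140046
#> 2:  g00130    g00130_p07 3.571173e-05 3.571173e-05 3.571173e-05         -400     TRUE 0.00140046
#> 3:  g00166    g00166_p07 3.571173e-05 3.571173e-05 3.571173e-05         -400     TRUE 0.00140046

rs <- recovery_stats(calls, truth)
#> positives: 104 of 100 planted; sensitivity 1.000, FDR 0.038
```

The best probes sit close to the TSS (the planted proximal binding
mode), their replicate p-values hit the resolution floor of the
empirical null (≈ 0.5/N_null), and the planted genes are recovered with
a 3.8% false discovery rate at the fixed thresholds — no tuning
involved.

## The analysis workflow

Numbered drivers under `analysis/` replay the whole study on a
four-thousand-promoter synthetic design (six factors, two
serum-induction time points, planted co-occupancy and persistence
structure) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # design + planted truth
Rscript analysis/02_probe_statistics.R    # scale spline, p-values, calibration
Rscript analysis/03_gene_calls.R          # replicate rule, gene calls, recovery
Rscript analysis/04_cooccupancy.R         # matrix, clustering, groups, overlap
Rscript analysis/05_tss_profiles.R        # distance-from-TSS profiles
Rscript analysis/06_expression_integration.R
Rscript analysis/07_motif_enrichment.R
Rscript analysis/08_qpcr_validation.R
```

Sample of what they print (each run is deterministic):

```
PRC  48h: 205 positive (planted 200, sens 0.995, fdr 0.029)
genes positive only for PRC: 36 of 205 PRC-positive (17.6%)
genes bound by all six factors: 44        # 45 planted
strongest co-occupancy: PRC/ERR1 (phi 0.666)
PRC : modal bin centre +1375 bp   NRF1: modal bin centre -375 bp
top enriched 8-mer: TGACGTCA (64/150 pos, 0/150 neg, p = 6.8e-19)
```

## Layout

```
R/                  package code (one file per stage)
tests/testthat/     unit, property and acceptance tests
analysis/           numbered workflow drivers
scripts/acceptance.R
vignettes/chipnet-methods.Rmd   methods and design rationale
```
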