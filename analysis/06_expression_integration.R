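#!/usr/bin/env Rscript
# Stage 6: expression side — miRNA-style total gene signal and QC
# regression, differential calling in a knockdown-vs-scramble design,
# integration with the ChIP gene calls, the miRNA promoter/expression
# intersection and the pathway filter.

source("analysis/00_config.R")

ann <- study_annotation()
truths <- study_truths(ann)
asn <- assign_probes(ann, ann$probes)

## miRNA-style expression with planted differentials (triplicates)
expr <- simulate_expression(866, n_reps_per_group = 3, background = 10,
                            de_fraction = 0.15, lfc = 2, low_fraction = 0.1,
                            sd = 0.2, seed = SEED + 20L)
qc <- qc_regression(expr$signal[, "ctrl_1"], expr$signal[, "ctrl_2"],
                    background = expr$background)
message(sprintf("replicate QC: slope %.3f, RMSD %.3f over %d features",
                qc$slope, qc$rmsd, qc$n))

keep <- background_filter(expr$signal, expr$background)
de <- differential(expr$signal[keep, ], expr$groups, "ctrl", "kd")
write_tsv(de[order(p)], "results/differential_features.tsv")
truth_kept <- expr$truth[match(rownames(expr$signal)[keep],
                               expr$truth$feature_id)]
sens <- mean(de$is_de[truth_kept$is_de])
message(sprintf("differential features: %d called, %.2f of planted recovered",
                sum(de$is_de), sens))

## percent of differential genes bound per factor/time point; the "up"
## group is planted to overlap the coactivator's 48h targets (30%)
pos_long <- data.table::rbindlist(lapply(c("24h", "48h"), function(tp)
  data.table::rbindlist(lapply(FACTORS, function(f) {
    comb <- study_combined(ann, truths, f, tp)
    gc <- call_genes(asn, comb, genes = ann$genes$gene_id)
    data.table::data.table(factor = f, timepoint = tp,
                           gene_id = gc$gene_id[gc$positive])
  }))))
set.seed(SEED + 21L)
prc48 <- truths$`48h`[factor == "PRC", gene_id]
de_genes <- list(
  up_24h = c(sample(prc48, 60),
             sample(setdiff(ann$genes$gene_id, prc48), 140)),
  down_24h = sample(ann$genes$gene_id, 200))
report <- integrate_chip_expression(de_genes, pos_long)
write_tsv(report, "results/integration_percent_positive.tsv")
message(sprintf("percent ChIP-positive in differential groups: %.1f-%.1f%%",
                min(report$percent), max(report$percent)))

## miRNA promoters: ChIP-positive at 48h vs differentially expressed
mir_pos <- unique(pos_long[timepoint == "48h" &
                             gene_id %in% ann$genes$gene_id[ann$genes$is_mirna],
                           gene_id])
set.seed(SEED + 22L)
confirmed <- sample(mir_pos, round(0.9 * length(mir_pos)))
de_mirnas <- c(confirmed, paste0(sample(setdiff(
  ann$genes$gene_id[ann$genes$is_mirna], mir_pos), 5), ""))
its <- intersect_mirna(mir_pos, de_mirnas)
message(sprintf("miRNA promoters ChIP-positive: %d; confirmed by expression: %d",
                length(mir_pos), length(its$both)))

## pathway filter over a synthetic miRNA x pathway p-value matrix
set.seed(SEED + 23L)
n_mir <- 12; n_path <- 101
pmat <- matrix(runif(n_mir * n_path), n_mir, n_path,
               dimnames = list(sprintf("mir-%02d", 1:n_mir),
                               sprintf("path%03d", 1:n_path)))
enriched <- sample(n_path, 26)              # planted enriched pathways
for (j in enriched) pmat[sample(n_mir, 5), j] <- exp(-runif(5, 3.5, 8))
pf <- pathway_filter(pmat, min_hits = 3, neglog_threshold = 3)
write_tsv(data.table::data.table(pathway = colnames(pf$neglog),
                                 t(pf$neglog)),
          "results/pathway_filter_neglogp.tsv")
message(sprintf("pathways kept by the -ln(p) > 3 in >= 3 miRNAs filter: %d of %d",
                length(pf$kept), n_path))
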