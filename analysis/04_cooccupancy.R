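#!/usr/bin/env Rscript
# Stage 4: the genes x factors occupancy matrix at 48h, its clustering,
# factor-combination groups, pairwise overlap statistics, and the
# 24h-vs-48h persistence proportions per factor.

source("analysis/00_config.R")

ann <- study_annotation()
truths <- study_truths(ann)
asn <- assign_probes(ann, ann$probes)

calls <- list(`24h` = list(), `48h` = list())
for (tp in c("24h", "48h")) {
  for (f in FACTORS) {
    comb <- study_combined(ann, truths, f, tp)
    calls[[tp]][[f]] <- call_genes(asn, comb, genes = ann$genes$gene_id)
  }
}

om <- build_matrix(calls$`48h`)
message(sprintf("occupancy matrix: %d genes positive for >=1 factor",
                nrow(om$scores)))
write_tsv(data.table::data.table(gene_id = rownames(om$scores), om$scores),
          "results/occupancy_matrix_48h.tsv")

cl <- cluster_rows(om)
write_dendrogram(cl, "results/occupancy_dendrogram_48h.nwk")

sizes <- combination_sizes(om)
write_tsv(sizes, "results/combination_sizes_48h.tsv")
excl_prc <- length(extract_groups(om, "PRC", exact = TRUE))
n_prc <- sum(om$positive[, "PRC"])
message(sprintf("genes positive only for PRC: %d of %d PRC-positive (%.1f%%)",
                excl_prc, n_prc, 100 * excl_prc / n_prc))
message(sprintf("genes bound by all six factors: %d",
                length(extract_groups(om, FACTORS, exact = TRUE))))

ov <- pairwise_overlap(om, universe_size = nrow(ann$genes))
write_tsv(ov[order(fisher_p)], "results/pairwise_overlap_48h.tsv")
top <- ov[order(-phi)][1]
message(sprintf("strongest co-occupancy: %s/%s (phi %.3f)",
                top$factor1, top$factor2, top$phi))

persist <- data.table::rbindlist(lapply(FACTORS, function(f)
  cbind(data.table::data.table(factor = f),
        compare_timepoints(calls$`24h`[[f]], calls$`48h`[[f]]))))
write_tsv(persist, "results/timepoint_persistence.tsv")
message("24h/48h persistence written to results/timepoint_persistence.tsv")
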