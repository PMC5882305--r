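#!/usr/bin/env Rscript
# Stage 1: build the synthetic study — a 4,000-promoter array (including
# 300 miRNA promoters) with six factors bound at two serum-induction
# time points — and record the planted ground truth.

source("analysis/00_config.R")

ann <- study_annotation()
truths <- study_truths(ann)

write_bed(ann, "results/annotation.bed")
write_tsv(truths$`24h`, "results/truth_24h.tsv")
write_tsv(truths$`48h`, "results/truth_48h.tsv")

message(sprintf("annotation: %d genes (%d miRNA promoters), %d probes",
                nrow(ann$genes), sum(ann$genes$is_mirna), nrow(ann$probes)))
for (tp in names(truths)) {
  n <- table(truths[[tp]]$factor)
  message(sprintf("planted truth %s: %s", tp,
                  paste(sprintf("%s=%d", names(n), n), collapse = " ")))
}

# one example array, written for inspection of the raw scatter
sim <- study_chip(ann, truths, "PRC", "48h")
write_tsv(sim$replicates[[1]][1:2000],
          "results/example_probe_table_PRC48_rep1_head.tsv")
message("wrote results/: annotation.bed, truth_{24h,48h}.tsv, example probe table")
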