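#!/usr/bin/env Rscript
# Stage 7: simplified motif analysis — probe contexts with a planted
# binding motif, enriched k-mer enumeration, PWM scanning, and the
# chi-square homogeneity test of score distributions.

source("analysis/00_config.R")

MOTIF <- "TGACGTCA"        # CRE-like planted site
seqs <- simulate_sequences(n_pos = 150, n_neg = 150, length = 460,
                           motif = MOTIF, plant_fraction = 0.5,
                           mask_fraction = 0.02, seed = SEED + 30L)
write_fasta(seqs$pos, "results/positive_contexts.fa")
write_fasta(seqs$neg, "results/negative_contexts.fa")

kt <- kmer_enrichment(seqs$pos, seqs$neg, k_range = c(8, 8))
write_tsv(kt[1:50], "results/kmer_enrichment_top50.tsv")
message(sprintf("top enriched 8-mer: %s (present in %d/%d pos, %d/%d neg, p = %.2e)",
                kt$kmer[1], kt$n_pos[1], length(seqs$pos), kt$n_neg[1],
                length(seqs$neg), kt$p[1]))
message(sprintf("planted motif (canonical %s) ranked %d",
                canonical_kmer(MOTIF),
                which(kt$kmer == canonical_kmer(MOTIF))[1]))

## PWM built from the planted motif with modest degeneracy
counts <- matrix(1, 4, nchar(MOTIF), dimnames = list(c("A", "C", "G", "T")))
for (j in seq_len(nchar(MOTIF)))
  counts[substr(MOTIF, j, j), j] <- 17     # 85% per consensus base
write_pfm(counts, "planted_cre_like", "results/planted_motif.pfm")
pwm <- make_pwm(counts, background = base_frequencies(seqs$neg))

pos_sc <- pwm_scan(seqs$pos, pwm)
neg_sc <- pwm_scan(seqs$neg, pwm)
ht <- motif_chisq(pos_sc$score, neg_sc$score)
write_tsv(data.table::data.table(set = rep(c("pos", "neg"),
                                           c(nrow(pos_sc), nrow(neg_sc))),
                                 rbind(pos_sc, neg_sc)),
          "results/pwm_scores.tsv")
message(sprintf("score homogeneity chi-square: %.1f (df %d), p = %.2e",
                ht$chi2, ht$df, ht$p))
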