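#' Assign probes to promoter windows with signed TSS distances
#'
#' A probe maps to a gene iff its position lies within
#' `[tss - window/2, tss + window/2)` (0-based, half-open) on the same
#' chromosome.  Distances are signed in the direction of transcription
#' (upstream negative): `pos - tss` on the + strand, `tss - pos` on the
#' - strand.  Probes on chromosomes absent from the annotation are
#' skipped with a warning and counted in attribute `n_skipped`.
#'
#' @param annotation a `chip_annotation` (or a data.table of genes with
#'   gene_id, chrom, tss, strand).
#' @param probes data.table with probe_id, chrom, pos.
#' @param window_bp promoter window; default the annotation's.
#' @return data.table(probe_id, gene_id, tss_distance); a probe may map
#'   to several overlapping promoters.
#' @export
assign_probes <- function(annotation, probes, window_bp = NULL) {
  genes <- if (inherits(annotation, "chip_annotation")) annotation$genes
           else data.table::as.data.table(annotation)
  if (is.null(window_bp)) {
    window_bp <- if (inherits(annotation, "chip_annotation"))
      annotation$window_bp else 8000L
  }
  probes <- data.table::as.data.table(probes)
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(probes)))
  unknown <- !(probes$chrom %in% unique(genes$chrom))
  if (any(unknown)) {
    warning(sprintf("%d probe(s) on chromosomes absent from the annotation; skipped",
                    sum(unknown)))
    probes <- probes[!unknown]
  }
  half <- window_bp / 2
  g <- data.table::data.table(gene_id = genes$gene_id, chrom = genes$chrom,
                              tss = genes$tss, strand = genes$strand,
                              lo = genes$tss - half, hi = genes$tss + half)
  hit <- probes[g, on = .(chrom, pos >= lo, pos < hi),
                .(probe_id = x.probe_id, gene_id = i.gene_id,
                  pos = x.pos, tss = i.tss, strand = i.strand),
                nomatch = NULL, allow.cartesian = TRUE]
  out <- hit[, .(probe_id, gene_id,
                 tss_distance = ifelse(strand == "+", pos - tss, tss - pos))]
  data.table::setattr(out, "n_skipped", sum(unknown))
  out[]
}

#' Combine two technical ChIP replicates per probe
#'
#' Applies the fixed conjunction rule for final positive probes:
#' `pVal1 * pVal2 < product_threshold` AND `pVal1 < rep_threshold` AND
#' `pVal2 < rep_threshold` (defaults 1e-3 and 1e-2), and records the
#' geometric mean sqrt(pVal1 * pVal2) for every probe.  `literal = TRUE`
#' switches to reading the threshold constants as 10e-3 = 0.01 and
#' 10e-2 = 0.1.
#'
#' @param rep1,rep2 data.tables with probe_id and p (e.g. from
#'   [probe_pvalues()]); probe_id sets must match exactly.
#' @param product_threshold,rep_threshold rule constants.
#' @param literal use the literal scientific-notation reading of the
#'   constants (0.01 / 0.1) instead of 1e-3 / 1e-2.
#' @return data.table(probe_id, pVal1, pVal2, gm, pass).
#' @export
combine_replicates <- function(rep1, rep2, product_threshold = 1e-3,
                               rep_threshold = 1e-2, literal = FALSE) {
  rep1 <- data.table::as.data.table(rep1)
  rep2 <- data.table::as.data.table(rep2)
  stopifnot(all(c("probe_id", "p") %in% names(rep1)),
            all(c("probe_id", "p") %in% names(rep2)))
  n_unmatched <- sum(!(rep1$probe_id %in% rep2$probe_id)) +
    sum(!(rep2$probe_id %in% rep1$probe_id))
  if (n_unmatched > 0)
    stop(sprintf("replicates have %d unmatched probe id(s)", n_unmatched))
  if (literal) { product_threshold <- 10e-3; rep_threshold <- 10e-2 }
  m <- merge(rep1[, .(probe_id, pVal1 = p)], rep2[, .(probe_id, pVal2 = p)],
             by = "probe_id")
  m[, gm := sqrt(pVal1 * pVal2)]
  m[, pass := (pVal1 * pVal2 < product_threshold) &
      (pVal1 < rep_threshold) & (pVal2 < rep_threshold)]
  m[]
}

#' Call positive genes from combined replicate p-values
#'
#' The best probe of a gene is the one minimising the geometric-mean
#' p-value (ties broken by smaller pVal1, then lexicographic probe id);
#' a gene is positive iff its best probe passes the replicate conjunction
#' rule, and, in strict mode, additionally has geometric mean <=
#' `gm_threshold` (the "geometric means ... considered when p <= 1e-3"
#' reading).  A Benjamini-Hochberg-adjusted column on best_gm is emitted
#' for information only; calling uses the fixed thresholds.
#'
#' @param assignments output of [assign_probes()].
#' @param combined output of [combine_replicates()].
#' @param genes optional character vector of the full gene universe;
#'   genes without assigned probes are emitted negative with NA best
#'   fields.
#' @param strict require best_gm <= gm_threshold in addition to the rule.
#' @param gm_threshold geometric-mean threshold for strict mode.
#' @return data.table(gene_id, best_probe_id, pVal1, pVal2, best_gm,
#'   tss_distance, positive, bh).
#' @export
call_genes <- function(assignments, combined, genes = NULL, strict = FALSE,
                       gm_threshold = 1e-3) {
  a <- data.table::as.data.table(assignments)
  m <- merge(a, data.table::as.data.table(combined), by = "probe_id")
  if (nrow(m) == 0) stop("no assigned probe has combined p-values")
  data.table::setorder(m, gene_id, gm, pVal1, probe_id)
  best <- m[, utils::head(.SD, 1L), by = gene_id,
            .SDcols = c("probe_id", "pVal1", "pVal2", "gm", "pass",
                        "tss_distance")]
  data.table::setnames(best, c("probe_id", "gm"),
                       c("best_probe_id", "best_gm"))
  best[, positive := pass & (!strict | best_gm <= gm_threshold)]
  best[, pass := NULL]
  if (!is.null(genes)) {
    best <- merge(data.table::data.table(gene_id = genes), best,
                  by = "gene_id", all.x = TRUE)
    best[is.na(positive), positive := FALSE]
  }
  best[, bh := stats::p.adjust(best_gm, method = "BH")]
  data.table::setcolorder(best, c("gene_id", "best_probe_id", "pVal1",
                                  "pVal2", "best_gm", "tss_distance",
                                  "positive", "bh"))
  best[]
}
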