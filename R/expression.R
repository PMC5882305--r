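#' Total gene signal of one feature
#'
#' Per-feature miRNA-array summary: the sum of the feature's probe
#' signals multiplied by the number of probes.
#'
#' @param signals numeric vector of probe signals for one feature.
#' @return scalar TGS.
#' @export
total_gene_signal <- function(signals) {
  if (length(signals) == 0) stop("feature has zero probes")
  sum(signals) * length(signals)
}

#' Total gene signal per feature and sample
#'
#' @param probe_dt data.table with feature_id, sample, signal (one row
#'   per probe x sample).
#' @return features x samples TGS matrix.
#' @export
tgs_matrix <- function(probe_dt) {
  dt <- data.table::as.data.table(probe_dt)
  stopifnot(all(c("feature_id", "sample", "signal") %in% names(dt)))
  agg <- dt[, .(tgs = sum(signal) * .N), by = .(feature_id, sample)]
  wide <- data.table::dcast(agg, feature_id ~ sample, value.var = "tgs")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$feature_id
  m
}

#' Between-sample QC regression of log total gene signals
#'
#' For features expressing above 10x the background level in both
#' samples, the natural logs of the total gene signals are regressed
#' against each other (ordinary least squares) and the standard deviation
#' of the residuals is reported as the root mean square deviation (RMSD).
#'
#' @param tgs_a,tgs_b TGS vectors of the two samples (matched features).
#' @param background scalar background level; the filter keeps features
#'   with TGS > 10 * background in both samples.
#' @param min_pass minimum number of passing features (default 10).
#' @return list(slope, intercept, rmsd, n).
#' @export
qc_regression <- function(tgs_a, tgs_b, background, min_pass = 10L) {
  stopifnot(length(tgs_a) == length(tgs_b))
  pass <- tgs_a > 10 * background & tgs_b > 10 * background
  if (sum(pass) < min_pass)
    stop(sprintf("only %d feature(s) exceed 10x background in both samples (need >= %d)",
                 sum(pass), min_pass))
  la <- log(tgs_a[pass]); lb <- log(tgs_b[pass])
  fit <- stats::lm(lb ~ la)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rmsd = stats::sd(stats::residuals(fit)),
       n = sum(pass))
}

#' Filter features above 10x background
#'
#' @param signal features x samples matrix (linear scale).
#' @param background scalar background level.
#' @param all_samples require the threshold in every sample (default) or
#'   in at least one.
#' @return logical vector over features.
#' @export
background_filter <- function(signal, background, all_samples = TRUE) {
  ok <- signal > 10 * background
  if (all_samples) rowSums(!ok) == 0 else rowSums(ok) > 0
}

#' Differential expression between two replicate groups
#'
#' Welch t-test per feature on log2 signals plus an absolute
#' fold-change criterion; a feature is differential iff the (unadjusted)
#' p-value is <= alpha and |log2 FC| >= log2(fc_threshold).  A
#' Benjamini-Hochberg column is reported for information.
#'
#' @param signal features x samples matrix (linear scale, typically
#'   pre-filtered with [background_filter()]).
#' @param groups named character vector sample -> group.
#' @param group_a,group_b the two group labels (FC is b over a).
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param alpha significance level (default 0.05).
#' @return data.table(feature_id, log2fc, t, p, bh, is_de).
#' @export
differential <- function(signal, groups, group_a, group_b,
                         fc_threshold = 2, alpha = 0.05) {
  sa <- names(groups)[groups == group_a]
  sb <- names(groups)[groups == group_b]
  if (length(sa) < 2 || length(sb) < 2)
    stop("each group needs >= 2 replicates")
  la <- log2(signal[, sa, drop = FALSE])
  lb <- log2(signal[, sb, drop = FALSE])
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- !is.finite(tstat)                    # zero variance in both groups
  p[degen] <- ifelse(abs(mb - ma)[degen] < 1e-12, 1, 0)
  lfc <- mb - ma
  data.table::data.table(
    feature_id = rownames(signal), log2fc = lfc, t = tstat, p = p,
    bh = stats::p.adjust(p, "BH"),
    is_de = p <= alpha & abs(lfc) >= log2(fc_threshold))
}

#' Percent of differential genes bound per factor and time point
#'
#' For each differential gene group (e.g. up at T24), each factor and
#' each ChIP time point, the percentage of the group's genes positive on
#' ChIP-chip.
#'
#' @param gene_groups named list of gene-id vectors.
#' @param positives data.table(factor, timepoint, gene_id) listing
#'   positive genes per factor/time point.
#' @return data.table(group, factor, timepoint, n_group, n_overlap,
#'   percent); percent is NA (with a warning) for empty groups.
#' @export
integrate_chip_expression <- function(gene_groups, positives) {
  pos <- data.table::as.data.table(positives)
  stopifnot(all(c("factor", "timepoint", "gene_id") %in% names(pos)))
  combos <- unique(pos[, .(factor, timepoint)])
  out <- list()
  for (g in names(gene_groups)) {
    grp <- unique(gene_groups[[g]])
    if (length(grp) == 0)
      warning(sprintf("gene group '%s' is empty; percent undefined", g))
    for (k in seq_len(nrow(combos))) {
      f <- combos$factor[k]; tp <- combos$timepoint[k]
      pset <- pos[factor == f & timepoint == tp, gene_id]
      ov <- length(intersect(grp, pset))
      out[[length(out) + 1L]] <- data.table::data.table(
        group = g, factor = f, timepoint = tp,
        n_group = length(grp), n_overlap = ov,
        percent = if (length(grp)) 100 * ov / length(grp) else NA_real_)
    }
  }
  data.table::rbindlist(out)
}

normalize_mirna_ids <- function(ids) sub("^hsa-", "", tolower(ids))

#' Intersect ChIP-positive miRNA promoters with differential miRNAs
#'
#' Ids are normalized (case-folded, "hsa-" prefix stripped) before the
#' set partition; `both` is the confirmed set supported by both ChIP and
#' expression.
#'
#' @param chip_mirnas miRNA ids whose promoters are ChIP-positive.
#' @param de_mirnas differentially expressed miRNA ids.
#' @return list(chip_only, de_only, both) of normalized ids.
#' @export
intersect_mirna <- function(chip_mirnas, de_mirnas) {
  a <- unique(normalize_mirna_ids(chip_mirnas))
  b <- unique(normalize_mirna_ids(de_mirnas))
  list(chip_only = setdiff(a, b), de_only = setdiff(b, a),
       both = intersect(a, b))
}

#' Filter a miRNA x pathway p-value matrix
#'
#' Keeps a pathway iff at least `min_hits` miRNAs are enriched for it at
#' -ln(p) > `neglog_threshold`.  Returns the -ln(p) matrix of kept
#' pathways, optionally with a "union" row holding, per pathway, the
#' -ln of the minimum p across miRNAs (the merged-miRNA representation).
#'
#' @param pmat miRNAs x pathways matrix of p-values in (0, 1].
#' @param min_hits minimum enriched miRNAs per kept pathway (default 3).
#' @param neglog_threshold -ln(p) threshold (default 3).
#' @param union_row append the union row (default TRUE).
#' @return list(kept = pathway names, neglog = -ln(p) matrix of kept
#'   pathways, n_hits = per-pathway hit counts over all pathways).
#' @export
pathway_filter <- function(pmat, min_hits = 3L, neglog_threshold = 3,
                           union_row = TRUE) {
  if (any(!is.finite(pmat)) || any(pmat <= 0) || any(pmat > 1))
    stop("p-values must lie in (0, 1]")
  nl <- -log(pmat)
  n_hits <- colSums(nl > neglog_threshold)
  kept <- colnames(pmat)[n_hits >= min_hits]
  m <- nl[, kept, drop = FALSE]
  if (union_row && length(kept))
    m <- rbind(m, union = apply(-log(pmat[, kept, drop = FALSE]), 2, max))
  list(kept = kept, neglog = m, n_hits = n_hits)
}
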