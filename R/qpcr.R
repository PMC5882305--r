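#' ChIP-qPCR fold enrichment vs IgG (2^-ddCt)
#'
#' ddCt = (mean Ct_IP - mean Ct_input) - (mean Ct_IgG - mean Ct_input);
#' the input term cancels algebraically but is accepted and checked as an
#' amplification sanity control.  The ChIP is called positive at a fold
#' enrichment of at least `fold_threshold` (default 3) over the
#' non-specific IgG fraction.
#'
#' @param ct_ip,ct_igg,ct_input numeric Ct vectors (cycles); `ct_input`
#'   may be NULL.
#' @param fold_threshold positivity threshold on the fold (default 3).
#' @return list(ddct, fold, positive).
#' @export
chip_fold_enrichment <- function(ct_ip, ct_igg, ct_input = NULL,
                                 fold_threshold = 3) {
  if (length(ct_ip) == 0) stop("ct_ip is empty")
  if (length(ct_igg) == 0)
    stop("the 3-fold rule is defined against IgG; ct_igg is required")
  .check_ct(c(ct_ip, ct_igg, ct_input))
  ref <- if (is.null(ct_input)) 0 else mean(ct_input)
  ddct <- (mean(ct_ip) - ref) - (mean(ct_igg) - ref)
  fold <- 2^(-ddct)
  # tolerance keeps an exactly threshold-fold enrichment on the >= side
  list(ddct = ddct, fold = fold,
       positive = fold >= fold_threshold * (1 - 1e-12))
}

.check_ct <- function(ct) {
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  if (any(ct < 10 | ct > 40))
    warning("Ct value(s) outside the typical 10-40 cycle range")
  invisible(ct)
}

#' Fold enrichment from a long-format Ct table
#'
#' Convenience wrapper over [chip_fold_enrichment()] for tables shaped
#' like [simulate_qpcr()] output (conditions IP, IgG, input).
#'
#' @param ct_table data.table with columns condition and ct.
#' @param fold_threshold positivity threshold (default 3).
#' @return list(ddct, fold, positive).
#' @export
qpcr_fold_from_table <- function(ct_table, fold_threshold = 3) {
  dt <- data.table::as.data.table(ct_table)
  stopifnot(all(c("condition", "ct") %in% names(dt)))
  inp <- dt[condition == "input", ct]
  chip_fold_enrichment(dt[condition == "IP", ct],
                       dt[condition == "IgG", ct],
                       if (length(inp)) inp else NULL,
                       fold_threshold = fold_threshold)
}

#' Relative expression vs a calibrator condition (2^-ddCt)
#'
#' Per-replicate dCt = Ct_target - Ct_reference (the reference being a
#' housekeeping amplicon such as beta-globin); ddCt is the mean dCt
#' difference between the test condition and the calibrator (e.g. T0),
#' fold = 2^-ddCt.  Significance is a two-sided Welch t-test on the
#' replicate dCt values (the approximately normal scale), significant at
#' p <= alpha.
#'
#' @param ct_target_t,ct_ref_t replicate Ct values in the test condition
#'   (target and reference amplicons, matched replicates).
#' @param ct_target_0,ct_ref_0 same for the calibrator condition.
#' @param alpha significance level (default 0.05).
#' @return list(ddct, fold, ci (95\% fold CI, NA with < 3 replicates),
#'   p, significant); p is NA with fewer than 2 replicates per condition.
#' @export
relative_expression <- function(ct_target_t, ct_ref_t, ct_target_0,
                                ct_ref_0, alpha = 0.05) {
  stopifnot(length(ct_target_t) == length(ct_ref_t),
            length(ct_target_0) == length(ct_ref_0))
  .check_ct(c(ct_target_t, ct_ref_t, ct_target_0, ct_ref_0))
  dct_t <- ct_target_t - ct_ref_t
  dct_0 <- ct_target_0 - ct_ref_0
  ddct <- mean(dct_t) - mean(dct_0)
  fold <- 2^(-ddct)
  if (length(dct_t) < 2 || length(dct_0) < 2)
    return(list(ddct = ddct, fold = fold, ci = c(NA_real_, NA_real_),
                p = NA_real_, significant = NA))
  if (stats::var(dct_t) < 1e-24 && stats::var(dct_0) < 1e-24) {
    p <- if (abs(ddct) < 1e-12) 1 else 0      # replicates exactly constant
    return(list(ddct = ddct, fold = fold, ci = c(fold, fold), p = p,
                significant = p <= alpha))
  }
  tt <- stats::t.test(dct_t, dct_0)
  ci <- rev(2^(-tt$conf.int))                 # monotone decreasing map
  list(ddct = ddct, fold = fold, ci = as.numeric(ci), p = tt$p.value,
       significant = tt$p.value <= alpha)
}
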