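#' Distance-from-TSS profile of positive probes
#'
#' Bins signed TSS distances (transcription direction, upstream negative)
#' into half-open bins `[lo, hi)` and reports, per bin, the number of
#' positive probes, the total number of assigned probes, and their ratio
#' (0 for empty bins), i.e. the fraction of probes positive at a given
#' distance from the TSS.
#'
#' @param assignments output of [assign_probes()] (probe_id,
#'   tss_distance).
#' @param probe_calls data.table with probe_id and a logical `pass`
#'   column (e.g. from [combine_replicates()]).
#' @param bin_width_bp bin width in bp (default 250).
#' @param range two-element distance range (default c(-4000, 4000)).
#' @return data.table(bin_lo, bin_hi, n_pos, n_tot, ratio).
#' @export
tss_profile <- function(assignments, probe_calls, bin_width_bp = 250,
                        range = c(-4000, 4000)) {
  if (bin_width_bp <= 0) stop("bin_width_bp must be positive")
  a <- data.table::as.data.table(assignments)
  m <- merge(a, data.table::as.data.table(probe_calls)[, .(probe_id, pass)],
             by = "probe_id")
  breaks <- seq(range[1], range[2], by = bin_width_bp)
  if (breaks[length(breaks)] < range[2])
    breaks <- c(breaks, range[2])
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  keep <- m$tss_distance >= range[1] & m$tss_distance < range[2]
  m <- m[keep]
  idx <- findInterval(m$tss_distance, breaks, rightmost.closed = FALSE)
  n_tot <- tabulate(idx, nbins = length(lo))
  n_pos <- tabulate(idx[m$pass], nbins = length(lo))
  data.table::data.table(bin_lo = lo, bin_hi = hi, n_pos = n_pos,
                         n_tot = n_tot,
                         ratio = ifelse(n_tot > 0, n_pos / n_tot, 0))
}

#' Modal bin and spread of a TSS binding profile
#'
#' The mode is the bin with the highest positive/total ratio, ties broken
#' toward the bin whose centre is nearest the TSS (then the lower bin).
#' Quartiles are computed over the positive probes' signed distances when
#' supplied.
#'
#' @param profile output of [tss_profile()].
#' @param distances optional vector of positive probes' signed distances
#'   for quantile summaries.
#' @return list(mode_lo, mode_hi, mode_center, n_pos, q25, q50, q75);
#'   NULL (with a warning) when there is no positive probe.
#' @export
peak_summary <- function(profile, distances = NULL) {
  if (sum(profile$n_pos) == 0) {
    warning("no positive probe; peak summary undefined")
    return(NULL)
  }
  ctr <- (profile$bin_lo + profile$bin_hi) / 2
  best <- which(profile$ratio == max(profile$ratio))
  best <- best[order(abs(ctr[best]), ctr[best])][1]
  q <- if (is.null(distances)) rep(NA_real_, 3)
       else unname(stats::quantile(distances, c(0.25, 0.5, 0.75)))
  list(mode_lo = profile$bin_lo[best], mode_hi = profile$bin_hi[best],
       mode_center = ctr[best], n_pos = sum(profile$n_pos),
       q25 = q[1], q50 = q[2], q75 = q[3])
}
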