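#' Normalize two-channel probe intensities
#'
#' Associates every probe with a pair (x, y) of normalized log2
#' intensities, x from the input (whole chromatin) channel and y from the
#' immunoprecipitated channel.  Each channel is log2-transformed and
#' median-centred, and the global median of the signed deviation
#' d = y - x is shifted to zero: the bulk of probes is assumed
#' non-enriched, so after centring they scatter symmetrically around the
#' x = y axis.
#'
#' @param raw data.frame/data.table with at least `probe_id`, `x_raw`,
#'   `y_raw` (positive linear intensities).  Extra columns (gene_id, pos,
#'   offset_bp, ...) are carried through.
#' @return data.table with columns probe_id, x, y, A = (x+y)/2,
#'   d = y - x, plus any carried columns.
#' @export
normalize_pairs <- function(raw) {
  raw <- data.table::as.data.table(raw)
  need <- c("probe_id", "x_raw", "y_raw")
  if (!all(need %in% names(raw)))
    stop("raw table must have columns probe_id, x_raw, y_raw")
  if (nrow(raw) == 0) stop("raw table is empty")
  bad <- which(!is.finite(raw$x_raw) | !is.finite(raw$y_raw) |
                 raw$x_raw <= 0 | raw$y_raw <= 0)
  if (length(bad))
    stop(sprintf("non-positive raw intensity for probe(s): %s",
                 paste(utils::head(raw$probe_id[bad], 5), collapse = ", ")))
  x <- log2(raw$x_raw) ; y <- log2(raw$y_raw)
  x <- x - stats::median(x)
  y <- y - stats::median(y)
  y <- y - stats::median(y - x)          # centre the null deviation
  out <- data.table::copy(raw)
  out[, c("x_raw", "y_raw") := NULL]
  out[, `:=`(x = x, y = y, A = (x + y) / 2, d = y - x)]
  out[]
}

#' Estimate the intensity-dependent null scale from reflected probes
#'
#' Probes below the identity axis (d < 0) are taken as a reflected sample
#' of the symmetric null.  Their |d| magnitudes are summarised per
#' equal-count intensity bin by a robust scale (median / 0.6745, the
#' normal-consistent MAD-type estimate), and a cubic smoothing spline
#' (generalized cross-validation) is fitted through the bin-wise scales,
#' giving the threshold-curve scale s(x) at any input intensity (the
#' horizontal axis of the input/IP scatter the threshold spline is drawn
#' in).  Evaluation is clamped to the observed intensity range at both
#' ends.
#'
#' @param pairs output of [normalize_pairs()].
#' @param n_bins number of equal-count intensity bins (default 20).
#' @return object of class `null_scale_model`: list with `bin_centers`,
#'   `s_bin`, `spline`, `range`, `n_null`, and `z_null` (sorted null
#'   magnitudes |d|/s(x) of the reflected sample, the empirical null
#'   reference).
#' @export
estimate_null <- function(pairs, n_bins = 20L) {
  stopifnot(all(c("x", "d") %in% names(pairs)))
  neg <- pairs[pairs$d < 0, ]
  if (nrow(neg) < 10 * n_bins)
    stop(sprintf(paste0("only %d probes below the x=y axis for %d bins ",
                        "(<10 per bin); use fewer bins"),
                 nrow(neg), n_bins))
  qs <- stats::quantile(neg$x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  qs <- unique(qs)
  bin <- cut(neg$x, breaks = qs, include.lowest = TRUE, labels = FALSE)
  cnt <- tabulate(bin, nbins = length(qs) - 1)
  if (any(cnt < 10))
    stop("a bin has fewer than 10 below-axis probes; use fewer bins")
  centers <- as.numeric(tapply(neg$x, bin, stats::median))
  s_bin <- as.numeric(tapply(abs(neg$d), bin, stats::median)) / 0.6745
  sp <- suppressWarnings(stats::smooth.spline(centers, s_bin, cv = FALSE))
  model <- structure(list(bin_centers = centers, s_bin = s_bin, spline = sp,
                          range = range(centers), n_null = nrow(neg),
                          z_null = NULL),
                     class = "null_scale_model")
  model$z_null <- sort(abs(neg$d) / predict_scale(model, neg$x))
  model
}

#' Evaluate the fitted null scale s(x)
#'
#' @param model a `null_scale_model`.
#' @param x input-channel intensities; values outside the fitted range
#'   are clamped.
#' @return positive scale values.
#' @export
predict_scale <- function(model, x) {
  stopifnot(inherits(model, "null_scale_model"))
  x <- pmin(pmax(x, model$range[1]), model$range[2])
  s <- stats::predict(model$spline, x)$y
  pmax(s, 0.25 * min(model$s_bin), 1e-8)
}

#' @export
print.null_scale_model <- function(x, ...) {
  cat(sprintf(paste0("null_scale_model: %d reflected probes, %d bins, ",
                     "s(x) in [%.3f, %.3f]\n"),
              x$n_null, length(x$bin_centers), min(x$s_bin), max(x$s_bin)))
  invisible(x)
}

# count of sorted null magnitudes >= z (ties count as >=)
.null_count_ge <- function(z_null, z) {
  length(z_null) - findInterval(z, z_null, left.open = TRUE)
}

#' Per-probe p-values from normalized distances to the x = y axis
#'
#' Computes z = d / s(x), the signed deviation toward the IP channel in
#' units of the local null spread, and a one-sided p-value for enrichment.
#' `gaussian`: the upper tail of the standard normal at z.  `empirical`
#' (default): the survival function of the symmetric null reconstructed
#' from the reflected below-axis sample; for z > 0,
#' p = (1 + #\{null |z_j| >= z\}) / (2 (1 + N_null)), and the mirrored
#' complement for z <= 0, so probes at or below the axis get p >= 0.5 and
#' strongly negative probes p near 1.  Ties count as >= (conservative).
#'
#' @param pairs output of [normalize_pairs()].
#' @param model `null_scale_model` fitted on the same pairs.
#' @param method `"empirical"` or `"gaussian"`.
#' @return data.table: the input columns plus z and p.
#' @export
probe_pvalues <- function(pairs, model, method = c("empirical", "gaussian")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "null_scale_model"))
  z <- pairs$d / predict_scale(model, pairs$x)
  if (method == "gaussian") {
    p <- stats::pnorm(z, lower.tail = FALSE)
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
  } else {
    N <- length(model$z_null)
    p <- numeric(length(z))
    up <- z > 0
    p[up]  <- 0.5 * (1 + .null_count_ge(model$z_null, z[up])) / (1 + N)
    p[!up] <- 1 - 0.5 * (1 + .null_count_ge(model$z_null, -z[!up])) / (1 + N)
  }
  out <- data.table::as.data.table(pairs)
  out[, `:=`(z = z, p = p)]
  out[]
}

#' Threshold spline curve at a given significance level
#'
#' Returns the curve d*(x) above the x = y axis (equivalently the
#' threshold spline curve y = x + d*(x) in the input/IP scatter) such
#' that a probe is classified positive (p < alpha) iff its deviation d
#' exceeds d*(x).  For the gaussian method d*(x) = s(x) * qnorm(1 -
#' alpha); for the empirical method the critical normalized distance is
#' the order statistic of the reflected null sample at which the
#' empirical p drops below alpha.
#'
#' @param model a `null_scale_model`.
#' @param alpha significance level in (0, 0.5].
#' @param method `"empirical"` or `"gaussian"`.
#' @param x input intensities at which to evaluate the curve; default a
#'   201-point grid over the fitted range.
#' @return data.table(x, d_star) with attribute `z_star` (the critical
#'   normalized distance).
#' @export
threshold_curve <- function(model, alpha, method = c("empirical", "gaussian"),
                            x = NULL) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 0.5)
    stop("alpha must be in (0, 0.5]")
  if (is.null(x))
    x <- seq(model$range[1], model$range[2], length.out = 201L)
  if (method == "gaussian") {
    z_star <- stats::qnorm(1 - alpha)
  } else {
    N <- length(model$z_null)
    # largest allowed count c with 0.5*(1+c)/(1+N) < alpha
    c_max <- ceiling(2 * alpha * (1 + N) - 1) - 1
    if (c_max < 0) {
      z_star <- Inf      # alpha below empirical resolution
    } else {
      z_desc <- rev(model$z_null)
      z_star <- z_desc[c_max + 1]
    }
  }
  out <- data.table::data.table(x = x,
                                d_star = z_star * predict_scale(model, x))
  data.table::setattr(out, "z_star", z_star)
  out
}
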