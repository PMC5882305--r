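#' Build a synthetic promoter-array annotation
#'
#' Creates a set of gene promoters on a single synthetic chromosome, each
#' tiled with probes across a window centred on the transcription start
#' site (TSS), mimicking a non-tiling promoter array where probes sparsely
#' sample an 8 kb region around each TSS.
#'
#' Probe offsets are signed in the direction of transcription (upstream
#' negative).  Each gene receives `floor(window_bp / probe_spacing_bp) + 1`
#' probes at offsets `seq(-window_bp/2, by = probe_spacing_bp)`.
#' Coordinates are 0-based, half-open.
#'
#' @param n_genes number of gene promoters.
#' @param n_mirna how many of the genes are miRNA promoters (flagged, not
#'   structurally different).
#' @param window_bp total promoter window size in bp (default 8000, i.e.
#'   +/- 4 kb around the TSS).
#' @param probe_spacing_bp spacing between consecutive probes in bp.
#' @param seed integer seed; fixing it fixes every output byte-for-byte.
#' @return an object of class `chip_annotation`: a list with elements
#'   `genes` (data.table: gene_id, chrom, tss, strand, is_mirna),
#'   `probes` (data.table: probe_id, gene_id, chrom, pos, offset_bp),
#'   `window_bp`, `probe_spacing_bp`.
#' @export
make_annotation <- function(n_genes, n_mirna = 0L, window_bp = 8000L,
                            probe_spacing_bp = 600L, seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (window_bp <= 0) stop("window_bp must be positive")
  if (probe_spacing_bp <= 0) stop("probe_spacing_bp must be positive")
  if (n_mirna > n_genes) stop("n_mirna cannot exceed n_genes")
  set.seed(seed)

  # genes laid out head-to-tail with a gap so promoter windows never overlap
  pitch <- window_bp + 2000L
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  if (n_mirna > 0) {
    mir_idx <- sort(sample.int(n_genes, n_mirna))
    gene_id[mir_idx] <- sprintf("mir%04d", seq_len(n_mirna))
  }
  genes <- data.table::data.table(
    gene_id = gene_id,
    chrom = "chrS",
    tss = as.integer(window_bp / 2 + pitch * (seq_len(n_genes) - 1L)),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    is_mirna = grepl("^mir", gene_id)
  )

  n_probes <- floor(window_bp / probe_spacing_bp) + 1L
  offset <- as.integer(seq(-window_bp / 2, by = probe_spacing_bp,
                           length.out = n_probes))
  gid <- rep(genes$gene_id, each = n_probes)
  tss_r <- rep(genes$tss, each = n_probes)
  str_r <- rep(genes$strand, each = n_probes)
  off_r <- rep(offset, times = n_genes)
  probes <- data.table::data.table(
    probe_id = sprintf("%s_p%02d", gid, rep(seq_len(n_probes), n_genes)),
    gene_id = gid,
    chrom = "chrS",
    pos = as.integer(ifelse(str_r == "+", tss_r + off_r, tss_r - off_r)),
    offset_bp = off_r)

  structure(list(genes = genes, probes = probes,
                 window_bp = as.integer(window_bp),
                 probe_spacing_bp = as.integer(probe_spacing_bp)),
            class = "chip_annotation")
}

#' @export
print.chip_annotation <- function(x, ...) {
  cat(sprintf("chip_annotation: %d genes (%d miRNA), %d probes, %d bp window\n",
              nrow(x$genes), sum(x$genes$is_mirna), nrow(x$probes),
              x$window_bp))
  invisible(x)
}

#' Plant per-factor binding truth on an annotation
#'
#' Selects a fraction of genes as truly bound for each factor and draws a
#' binding-centre offset from the TSS for every bound gene.  "proximal"
#' factors centre near the TSS (default N(-250, 300) bp) and "downstream"
#' factors inside the transcribed region (default N(+1500, 700) bp),
#' reproducing the qualitative contrast between promoter-proximal factors
#' and factors binding in the first exon.
#'
#' @param annotation a `chip_annotation`.
#' @param factors character vector of factor names.
#' @param bound_fraction fraction of genes truly bound per factor.
#' @param effect enrichment effect size at the binding centre, in units of
#'   the local null spread.
#' @param profile named character vector mapping each factor to
#'   `"proximal"` or `"downstream"`; defaults to proximal for all.
#' @param proximal_mean,proximal_sd,downstream_mean,downstream_sd normal
#'   parameters (bp, signed transcription-direction offsets) for the two
#'   binding-centre profiles.
#' @param seed integer seed.
#' @return data.table with columns factor, gene_id, center_offset, effect.
#' @export
make_truth <- function(annotation, factors, bound_fraction = 0.05,
                       effect = 6, profile = NULL,
                       proximal_mean = -250, proximal_sd = 300,
                       downstream_mean = 1500, downstream_sd = 700,
                       seed = 1L) {
  stopifnot(inherits(annotation, "chip_annotation"))
  if (bound_fraction < 0 || bound_fraction > 1)
    stop("bound_fraction must be in [0, 1]")
  if (effect < 0) stop("effect sizes must be >= 0")
  if (is.null(profile)) profile <- stats::setNames(rep("proximal",
                                                       length(factors)), factors)
  set.seed(seed)
  n_bound <- round(nrow(annotation$genes) * bound_fraction)
  out <- lapply(factors, function(f) {
    gid <- sample(annotation$genes$gene_id, n_bound)
    if (identical(profile[[f]], "downstream")) {
      ctr <- stats::rnorm(n_bound, downstream_mean, downstream_sd)
    } else {
      ctr <- stats::rnorm(n_bound, proximal_mean, proximal_sd)
    }
    data.table::data.table(factor = f, gene_id = gid,
                           center_offset = ctr, effect = effect)
  })
  data.table::rbindlist(out)
}

default_null_sd_fn <- function(base_mean, base_sd) {
  a0 <- base_mean - 3 * base_sd
  function(A) 0.2 + 0.6 * exp(-(pmax(A, a0) - a0) / 2)
}

#' Simulate two-channel ChIP-chip replicates
#'
#' Emulates the input/IP probe scatter of a promoter array: every probe
#' draws a base log2 abundance `x`; under the null the IP channel is
#' `y = x + eps` with `eps` symmetric around zero and an
#' intensity-dependent spread, so non-enriched probes scatter
#' symmetrically around the x=y axis.  Probes of bound genes gain an
#' additive IP-channel shift `effect * sd * K(dist/kernel_width_bp)`
#' where `K(u) = max(0, 1 - u)` is a triangular kernel peaking at the
#' binding centre.  Technical replicates share the truth and draw
#' independent noise.
#'
#' @param annotation a `chip_annotation`.
#' @param truth data.table with columns gene_id, center_offset, effect for
#'   a single factor (as one factor's rows of [make_truth()]), or `NULL`
#'   for a pure-null simulation.
#' @param base_mean,base_sd normal parameters of the base log2 abundance.
#' @param null_sd_fn vectorised function of intensity giving the null
#'   spread of `y - x`; default `0.2 + 0.6 * exp(-(A - A0)/2)` with
#'   `A0 = base_mean - 3 * base_sd`, so dim probes are noisier.
#' @param kernel_width_bp half-width of the triangular enrichment kernel.
#' @param n_replicates number of technical replicates (>= 1).
#' @param noise `"gaussian"` (default) or `"t"` for a heavy-tailed scaled
#'   t (df = 5) null; both are symmetric.
#' @param seed integer seed.
#' @return list with `replicates` (list of data.tables: probe_id, gene_id,
#'   chrom, pos, offset_bp, x_raw, y_raw on the linear intensity scale)
#'   and `truth` (the truth table used, possibly empty).
#' @export
simulate_chip <- function(annotation, truth = NULL, base_mean = 10,
                          base_sd = 1.5, null_sd_fn = NULL,
                          kernel_width_bp = 1000, n_replicates = 2L,
                          noise = c("gaussian", "t"), seed = 1L) {
  stopifnot(inherits(annotation, "chip_annotation"))
  noise <- match.arg(noise)
  if (kernel_width_bp <= 0) stop("kernel_width_bp must be positive")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (is.null(null_sd_fn)) null_sd_fn <- default_null_sd_fn(base_mean, base_sd)
  if (is.null(truth)) {
    truth <- data.table::data.table(gene_id = character(),
                                    center_offset = numeric(),
                                    effect = numeric())
  }
  if (nrow(truth) && !all(truth$gene_id %in% annotation$genes$gene_id))
    stop("truth refers to gene_ids absent from the annotation")
  if (nrow(truth) && any(truth$effect < 0)) stop("effect sizes must be >= 0")

  probes <- annotation$probes
  # deterministic per-probe enrichment weight (shared across replicates)
  shift_w <- numeric(nrow(probes))
  if (nrow(truth)) {
    idx <- match(probes$gene_id, truth$gene_id)
    hit <- !is.na(idx)
    u <- abs(probes$offset_bp[hit] - truth$center_offset[idx[hit]]) /
      kernel_width_bp
    shift_w[hit] <- truth$effect[idx[hit]] * pmax(0, 1 - u)
  }

  set.seed(seed)
  n <- nrow(probes)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    x <- stats::rnorm(n, base_mean, base_sd)
    s <- null_sd_fn(x)
    eps <- if (noise == "gaussian") stats::rnorm(n, 0, s) else
      stats::rt(n, df = 5) * s / sqrt(5 / 3)
    y <- x + eps + shift_w * s
    reps[[r]] <- data.table::data.table(
      probe_id = probes$probe_id, gene_id = probes$gene_id,
      chrom = probes$chrom, pos = probes$pos, offset_bp = probes$offset_bp,
      x_raw = 2^x, y_raw = 2^y)
  }
  list(replicates = reps, truth = truth)
}

#' Simulate a replicated two-group expression matrix
#'
#' Two groups (e.g. scramble vs knockdown siRNA) with shared feature means
#' for non-differential features; a planted fraction of features is
#' shifted by `lfc` (log2, random sign) in the second group, and a stated
#' fraction is simulated below 10x the background level to exercise the
#' quality filter.
#'
#' @param n_features number of features (genes or miRNAs).
#' @param n_reps_per_group replicates per group (>= 2).
#' @param background scalar background signal level (linear scale).
#' @param de_fraction fraction of features planted as differential.
#' @param lfc absolute planted log2 fold change.
#' @param low_fraction fraction of features simulated below the 10x
#'   background threshold.
#' @param sd replicate noise sd on the log2 scale.
#' @param seed integer seed.
#' @return list with `signal` (features x samples matrix, linear scale),
#'   `groups` (named character vector sample -> group), `background`, and
#'   `truth` (data.table: feature_id, is_de, true_lfc, low_expressed).
#' @export
simulate_expression <- function(n_features, n_reps_per_group = 3L,
                                background = 10, de_fraction = 0.1,
                                lfc = 2, low_fraction = 0.1, sd = 0.2,
                                seed = 1L) {
  if (n_reps_per_group < 2) stop("n_reps_per_group must be >= 2")
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  set.seed(seed)
  feature_id <- sprintf("f%05d", seq_len(n_features))
  n_de <- round(n_features * de_fraction)
  n_low <- round(n_features * low_fraction)
  is_de <- rep(FALSE, n_features)
  if (n_de > 0) is_de[sample.int(n_features, n_de)] <- TRUE
  low <- rep(FALSE, n_features)
  low_pool <- which(!is_de)
  if (n_low > 0) low[sample(low_pool, min(n_low, length(low_pool)))] <- TRUE

  # expressed features span a realistic dynamic range; low features sit
  # below the 10x-background QC threshold
  base <- ifelse(low, log2(3 * background),
                 log2(100 * background) + stats::rnorm(n_features, 0, 1.5))
  true_lfc <- ifelse(is_de, lfc * sample(c(-1, 1), n_features, TRUE), 0)

  samples <- c(sprintf("ctrl_%d", seq_len(n_reps_per_group)),
               sprintf("kd_%d", seq_len(n_reps_per_group)))
  groups <- stats::setNames(rep(c("ctrl", "kd"), each = n_reps_per_group),
                            samples)
  mu <- cbind(matrix(base, n_features, n_reps_per_group),
              matrix(base + true_lfc, n_features, n_reps_per_group))
  signal <- 2^(mu + matrix(stats::rnorm(length(mu), 0, sd), nrow(mu)))
  dimnames(signal) <- list(feature_id, samples)
  list(signal = signal, groups = groups, background = background,
       truth = data.table::data.table(feature_id = feature_id,
                                      is_de = is_de, true_lfc = true_lfc,
                                      low_expressed = low))
}

#' Simulate a qPCR Ct table for ChIP validation
#'
#' Generates cycle-threshold values for IP, IgG and input fractions such
#' that the expected 2^-ddCt enrichment of IP over IgG equals
#' `true_fold`; each halving of Ct corresponds to a doubling of template.
#'
#' @param true_fold expected IP/IgG fold enrichment (> 0).
#' @param ct_reference mean Ct of the IgG fraction.
#' @param noise_sd per-well Ct noise sd (cycles).
#' @param n_wells wells per fraction.
#' @param target label for the amplicon.
#' @param seed integer seed.
#' @return data.table with columns target, condition (IP/IgG/input),
#'   replicate, ct.
#' @export
simulate_qpcr <- function(true_fold, ct_reference = 28, noise_sd = 0.2,
                          n_wells = 3L, target = "amplicon", seed = 1L) {
  if (true_fold <= 0) stop("true_fold must be > 0")
  set.seed(seed)
  mk <- function(cond, mu) data.table::data.table(
    target = target, condition = cond, replicate = seq_len(n_wells),
    ct = mu + stats::rnorm(n_wells, 0, noise_sd))
  data.table::rbindlist(list(
    mk("IP", ct_reference - log2(true_fold)),
    mk("IgG", ct_reference),
    mk("input", ct_reference - 5)))
}

#' Simulate probe-context sequences with a planted motif
#'
#' Generates random uppercase DNA contexts (probe plus flanks) and plants
#' a motif instance, on a random strand at a random position, in a stated
#' fraction of the positive set.  A fraction of positions can be
#' lower-cased to mimic repeat masking.
#'
#' @param n_pos,n_neg numbers of positive/negative sequences.
#' @param length sequence length in bp (default 460 = 60-mer probe + 2x200
#'   flanks).
#' @param motif planted motif string (uppercase ACGT).
#' @param plant_fraction fraction of positive sequences carrying the motif.
#' @param mask_fraction fraction of positions lower-cased (soft-masked).
#' @param seed integer seed.
#' @return list with `pos`, `neg` (named character vectors) and `truth`
#'   (data.table: seq_id, planted, position, strand).
#' @export
simulate_sequences <- function(n_pos, n_neg, length = 460L,
                               motif = "TGACGTCA", plant_fraction = 0.5,
                               mask_fraction = 0, seed = 1L) {
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be uppercase ACGT")
  set.seed(seed)
  rand_seq <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, TRUE), collapse = ""), "")
  pos <- rand_seq(n_pos); neg <- rand_seq(n_neg)
  names(pos) <- sprintf("pos%04d", seq_len(n_pos))
  names(neg) <- sprintf("neg%04d", seq_len(n_neg))
  planted <- seq_len(n_pos) <= round(n_pos * plant_fraction)
  w <- nchar(motif)
  at <- rep(NA_integer_, n_pos); strand <- rep(NA_character_, n_pos)
  for (i in which(planted)) {
    at[i] <- sample.int(length - w + 1L, 1L)
    strand[i] <- sample(c("+", "-"), 1L)
    ins <- if (strand[i] == "+") motif else revcomp(motif)
    substr(pos[i], at[i], at[i] + w - 1L) <- ins
  }
  mask <- function(s) {
    if (mask_fraction <= 0) return(s)
    ch <- strsplit(s, "")[[1]]
    k <- sample.int(length(ch), round(length(ch) * mask_fraction))
    ch[k] <- tolower(ch[k])
    paste(ch, collapse = "")
  }
  if (mask_fraction > 0) {
    pos <- vapply(pos, mask, "")
    neg <- vapply(neg, mask, "")
  }
  list(pos = pos, neg = neg,
       truth = data.table::data.table(seq_id = names(pos), planted = planted,
                                      position = at, strand = strand))
}
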