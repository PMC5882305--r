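#' Reverse complement of DNA strings
#'
#' Case-preserving reverse complement (soft-masked lowercase stays
#' lowercase).
#'
#' @param x character vector of DNA strings.
#' @return character vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Extract a probe's sequence context with flanks
#'
#' Returns the probe sequence extended by `flank` bp on each side,
#' truncated (with a warning) at the sequence ends.  Case is preserved:
#' lower-case (repeat-masked) positions are excluded from scoring by the
#' downstream scanners.
#'
#' @param genome_seq a single character string (one chromosome/contig).
#' @param start,end probe coordinates, 0-based half-open.
#' @param flank flank size in bp (default 200).
#' @return character string.
#' @export
extract_context <- function(genome_seq, start, end, flank = 200L) {
  n <- nchar(genome_seq)
  if (start < 0 || end > n || end <= start)
    stop("probe coordinates out of genome bounds")
  lo <- start - flank
  hi <- end + flank
  if (lo < 0 || hi > n) {
    warning("context truncated at sequence boundary")
    lo <- max(lo, 0); hi <- min(hi, n)
  }
  substr(genome_seq, lo + 1L, hi)            # 0-based half-open -> substr
}

# unique valid (uppercase ACGT) k-mers of one sequence
.seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  km <- substring(seq, 1:(n - k + 1), k:n)
  unique(km[grepl("^[ACGT]+$", km)])
}

#' Canonical form of k-mers over reverse complement
#'
#' @param kmers character vector of uppercase k-mers.
#' @return the lexicographic minimum of each k-mer and its reverse
#'   complement.
#' @export
canonical_kmer <- function(kmers) {
  if (length(kmers) == 0) return(character())
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Rank k-mers enriched in positive vs negative sequences
#'
#' Simplified motif stand-in: per canonical k-mer (collapsed with its
#' reverse complement), the number of positive and negative sequences
#' containing it, a 2x2 chi-square with continuity correction, and a
#' pseudo-count fold enrichment; ranked by p then fold.  Soft-masked
#' (lowercase) and ambiguous positions never contribute k-mers.
#'
#' @param pos_seqs,neg_seqs character vectors of sequences.
#' @param k_range two-element integer range of k (within 7..18; default
#'   c(7, 10)).
#' @return data.table(kmer, k, n_pos, n_neg, fold, chi2, p).
#' @export
kmer_enrichment <- function(pos_seqs, neg_seqs, k_range = c(7L, 10L)) {
  if (length(pos_seqs) == 0 || length(neg_seqs) == 0)
    stop("both sequence sets must be non-empty")
  if (k_range[1] < 7 || k_range[2] > 18 || k_range[1] > k_range[2])
    stop("k_range must lie within [7, 18]")
  np <- length(pos_seqs); nn <- length(neg_seqs)
  out <- list()
  for (k in seq(k_range[1], k_range[2])) {
    pk <- lapply(pos_seqs, .seq_kmers, k = k)
    nk <- lapply(neg_seqs, .seq_kmers, k = k)
    pc <- table(unlist(lapply(pk, function(x) unique(canonical_kmer(x)))))
    ncnt <- table(unlist(lapply(nk, function(x) unique(canonical_kmer(x)))))
    kmers <- union(names(pc), names(ncnt))
    if (length(kmers) == 0) next
    a <- as.integer(pc[kmers]); a[is.na(a)] <- 0L
    b <- as.integer(ncnt[kmers]); b[is.na(b)] <- 0L
    # 2x2: present/absent x pos/neg, Yates-corrected chi-square
    cc <- np - a; dd <- nn - b
    N <- np + nn
    num <- N * pmax(abs(a * dd - b * cc) - N / 2, 0)^2
    den <- as.numeric(a + b) * (cc + dd) * np * nn
    chi2 <- ifelse(den > 0, num / den, 0)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    fold <- ((a + 0.5) / (np + 1)) / ((b + 0.5) / (nn + 1))
    out[[length(out) + 1L]] <- data.table::data.table(
      kmer = kmers, k = k, n_pos = a, n_neg = b, fold = fold,
      chi2 = chi2, p = p)
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, p, -fold, kmer)
  res[]
}

#' Build a log-odds position weight matrix
#'
#' Converts a 4 x width count (or frequency) matrix into per-column
#' probabilities with a pseudocount, and log2-odds against a 0-order
#' background.
#'
#' @param counts 4 x width numeric matrix, rows A, C, G, T.
#' @param background length-4 background probabilities (default uniform);
#'   typically estimated from the negative sequence set with
#'   [base_frequencies()].
#' @param pseudocount added to every cell (default 0.5).
#' @return object of class `pwm_model`: list(logodds, probs, consensus,
#'   width, background).
#' @export
make_pwm <- function(counts, background = rep(0.25, 4), pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  w <- ncol(counts)
  if (w < 7 || w > 18) stop("motif width must be within [7, 18]")
  if (any(abs(sum(background) - 1) > 1e-6)) stop("background must sum to 1")
  rownames(counts) <- c("A", "C", "G", "T")
  probs <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  logodds <- log2(sweep(probs, 1, background, "/"))
  consensus <- paste(rownames(counts)[apply(probs, 2, which.max)],
                     collapse = "")
  structure(list(logodds = logodds, probs = probs, consensus = consensus,
                 width = w, background = background), class = "pwm_model")
}

#' 0-order nucleotide frequencies of a sequence set
#'
#' @param seqs character vector (only uppercase ACGT positions counted).
#' @return named length-4 probability vector (A, C, G, T).
#' @export
base_frequencies <- function(seqs) {
  ch <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  tab <- table(factor(ch, levels = c("A", "C", "G", "T")))
  stats::setNames(as.numeric(tab) / sum(tab), c("A", "C", "G", "T"))
}

.scan_one <- function(seq, lo) {
  w <- ncol(lo)
  n <- nchar(seq)
  if (n < w) return(c(score = -Inf, offset = NA_real_))
  idx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  best <- -Inf; at <- NA_real_
  for (s in 1:(n - w + 1)) {
    ii <- idx[s:(s + w - 1)]
    if (anyNA(ii)) next                       # masked or ambiguous base
    sc <- sum(lo[cbind(ii, seq_len(w))])
    if (sc > best) { best <- sc; at <- s }
  }
  c(score = best, offset = at)
}

#' Scan sequences with a position weight matrix
#'
#' Best log-odds window per sequence over both strands; windows touching
#' soft-masked (lowercase) or ambiguous positions are excluded.  Fully
#' masked or too-short sequences get a -Inf sentinel score.
#'
#' @param seqs named character vector of sequences.
#' @param pwm a `pwm_model`.
#' @return data.table(seq_id, score, offset, strand); offset is the
#'   1-based start of the best window on the forward sequence.
#' @export
pwm_scan <- function(seqs, pwm) {
  stopifnot(inherits(pwm, "pwm_model"))
  ids <- if (is.null(names(seqs))) sprintf("seq%04d", seq_along(seqs))
         else names(seqs)
  w <- pwm$width
  out <- lapply(seq_along(seqs), function(i) {
    fwd <- .scan_one(seqs[[i]], pwm$logodds)
    rev <- .scan_one(revcomp(seqs[[i]]), pwm$logodds)
    n <- nchar(seqs[[i]])
    if (rev["score"] > fwd["score"]) {
      data.table::data.table(seq_id = ids[i], score = unname(rev["score"]),
                             offset = n - (unname(rev["offset"]) + w - 1) + 1,
                             strand = "-")
    } else {
      data.table::data.table(seq_id = ids[i], score = unname(fwd["score"]),
                             offset = unname(fwd["offset"]),
                             strand = ifelse(is.finite(fwd["score"]), "+",
                                             NA_character_))
    }
  })
  data.table::rbindlist(out)
}

#' Chi-square homogeneity test of motif scores
#'
#' Bins the pooled scores on quantiles, merges sparse tail bins until
#' every expected count is >= 5 (down to 2 bins), and tests homogeneity
#' of the positive vs negative score distributions with a 2 x K
#' chi-square (df = K - 1, no continuity correction).  Being
#' quantile-based, the test is invariant to monotone transforms of the
#' score.
#'
#' @param pos_scores,neg_scores numeric score vectors (non-finite values
#'   dropped).
#' @param n_bins initial number of quantile bins (default 10).
#' @return list(chi2, df, p, table).
#' @export
motif_chisq <- function(pos_scores, neg_scores, n_bins = 10L) {
  pos <- pos_scores[is.finite(pos_scores)]
  neg <- neg_scores[is.finite(neg_scores)]
  if (length(pos) == 0 || length(neg) == 0)
    stop("need finite scores in both sets")
  pooled <- c(pos, neg)
  if (length(unique(pooled)) == 1)
    return(list(chi2 = 0, df = 0, p = 1,
                table = matrix(c(length(pos), length(neg)), 2,
                               dimnames = list(c("pos", "neg"), NULL))))
  breaks <- unique(stats::quantile(pooled,
                                   probs = seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE))
  if (length(breaks) < 3) breaks <- c(min(pooled), stats::median(pooled),
                                      max(pooled))
  bin_of <- function(x) cut(x, breaks = breaks, include.lowest = TRUE,
                            labels = FALSE)
  tab <- rbind(pos = tabulate(bin_of(pos), nbins = length(breaks) - 1),
               neg = tabulate(bin_of(neg), nbins = length(breaks) - 1))
  # merge from the tails until expected counts reach 5
  repeat {
    if (ncol(tab) <= 2) break
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(exp_tab >= 5)) break
    j <- which.min(apply(exp_tab, 2, min))    # sparsest bin, merged inward
    k <- if (j == 1) 2L else j - 1L
    tab[, min(j, k)] <- tab[, j] + tab[, k]
    tab <- tab[, -max(j, k), drop = FALSE]
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), table = tab)
}
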