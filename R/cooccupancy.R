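#' Build the genes x factors occupancy matrix
#'
#' Rows are the union of genes positive for at least one factor (sorted
#' lexicographically for a deterministic pre-clustering order); a cell
#' holds -log10 of the best-probe geometric-mean p-value when the gene is
#' positive for that factor, 0 otherwise.
#'
#' @param calls named list of [call_genes()] tables, one per factor.
#' @return object of class `occupancy_matrix`: list with `scores`
#'   (numeric matrix), `positive` (logical matrix).
#' @export
build_matrix <- function(calls) {
  if (length(calls) < 1) stop("need at least one factor")
  if (is.null(names(calls)) || any(names(calls) == ""))
    stop("calls must be a named list (factor names)")
  pos_sets <- lapply(calls, function(dt) dt$gene_id[dt$positive])
  genes <- sort(unique(unlist(pos_sets)))
  if (length(genes) == 0) stop("no gene is positive for any factor")
  scores <- matrix(0, length(genes), length(calls),
                   dimnames = list(genes, names(calls)))
  positive <- matrix(FALSE, length(genes), length(calls),
                     dimnames = dimnames(scores))
  for (f in names(calls)) {
    dt <- calls[[f]]
    sel <- dt$positive & dt$gene_id %in% genes
    positive[dt$gene_id[sel], f] <- TRUE
    scores[dt$gene_id[sel], f] <- -log10(pmax(dt$best_gm[sel],
                                              .Machine$double.xmin))
  }
  structure(list(scores = scores, positive = positive),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("occupancy_matrix: %d positive genes x %d factors\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Hierarchically cluster occupancy-matrix rows
#'
#' Euclidean distance on -log10(p) scores capped at `cap` (so a few
#' extreme p-values cannot dominate), average linkage by default.
#'
#' @param om an `occupancy_matrix`.
#' @param linkage hclust agglomeration method.
#' @param metric dist metric.
#' @param cap cap applied to the score matrix before distances.
#' @return list with `order` (gene ids in leaf order) and `hclust` (NULL
#'   for a single row).
#' @export
cluster_rows <- function(om, linkage = "average", metric = "euclidean",
                         cap = 10) {
  stopifnot(inherits(om, "occupancy_matrix"))
  X <- pmin(om$scores, cap)
  if (nrow(X) < 2)
    return(list(order = rownames(X), hclust = NULL))
  h <- stats::hclust(stats::dist(X, method = metric), method = linkage)
  list(order = rownames(X)[h$order], hclust = h)
}

#' Write a row dendrogram as Newick
#'
#' @param clust result of [cluster_rows()] (needs a non-NULL hclust).
#' @param path output file.
#' @export
write_dendrogram <- function(clust, path) {
  if (is.null(clust$hclust)) stop("no dendrogram for a single row")
  ape::write.tree(ape::as.phylo(clust$hclust), file = path)
  invisible(path)
}

#' Extract a factor-combination group
#'
#' With `exact = TRUE`, genes positive for every factor in `factor_set`
#' and for no factor outside it (the combination groups whose sizes
#' partition the positive-gene universe); with `exact = FALSE`, any gene
#' positive for all factors of the set.
#'
#' @param om an `occupancy_matrix`.
#' @param factor_set character vector of factor names (subset of columns).
#' @param exact exact-combination semantics (default TRUE).
#' @return character vector of gene ids.
#' @export
extract_groups <- function(om, factor_set, exact = TRUE) {
  stopifnot(inherits(om, "occupancy_matrix"))
  if (!all(factor_set %in% colnames(om$positive)))
    stop(sprintf("unknown factor(s): %s",
                 paste(setdiff(factor_set, colnames(om$positive)),
                       collapse = ", ")))
  P <- om$positive
  in_set <- colnames(P) %in% factor_set
  keep <- if (any(in_set)) rowSums(!P[, in_set, drop = FALSE]) == 0
          else rep(TRUE, nrow(P))
  if (exact && any(!in_set))
    keep <- keep & rowSums(P[, !in_set, drop = FALSE]) == 0
  rownames(P)[keep]
}

#' Sizes of all exact factor-combination groups
#'
#' @param om an `occupancy_matrix`.
#' @return data.table(combination, n_genes), one row per observed exact
#'   combination; sizes sum to the number of matrix rows.
#' @export
combination_sizes <- function(om) {
  stopifnot(inherits(om, "occupancy_matrix"))
  sig <- apply(om$positive, 1, function(r)
    paste(colnames(om$positive)[r], collapse = "+"))
  tab <- table(sig)
  data.table::data.table(combination = names(tab),
                         n_genes = as.integer(tab))[order(-n_genes)]
}

#' Pairwise factor co-occupancy statistics
#'
#' For every factor pair, the 2x2 contingency table of positive calls
#' over a gene universe of `universe_size` genes (by default all genes on
#' the array, not only positives, to avoid conditioning bias), with the
#' phi coefficient, the (uncorrected) chi-square statistic, and the
#' two-sided Fisher exact p-value.
#'
#' @param om an `occupancy_matrix`.
#' @param universe_size number of genes in the testing universe; must be
#'   at least the number of matrix rows.
#' @return data.table(factor1, factor2, a, b, c, d, phi, chi2, fisher_p).
#' @export
pairwise_overlap <- function(om, universe_size) {
  stopifnot(inherits(om, "occupancy_matrix"))
  if (universe_size < nrow(om$positive))
    stop("universe_size is smaller than the observed positive-gene union")
  P <- om$positive
  fs <- colnames(P)
  out <- list()
  for (i in seq_along(fs)) for (j in seq_along(fs)) {
    if (j <= i) next
    a <- sum(P[, i] & P[, j])
    b <- sum(P[, i] & !P[, j])
    cc <- sum(!P[, i] & P[, j])
    dd <- universe_size - a - b - cc
    tab <- matrix(c(a, cc, b, dd), 2)
    phi <- (a * dd - b * cc) /
      sqrt(prod(c(a + b, cc + dd, a + cc, b + dd)))
    chi2 <- sum(tab) * (a * dd - b * cc)^2 /
      prod(c(a + b, cc + dd, a + cc, b + dd))
    fp <- stats::fisher.test(tab)$p.value
    out[[length(out) + 1L]] <- data.table::data.table(
      factor1 = fs[i], factor2 = fs[j], a = a, b = b, c = cc, d = dd,
      phi = phi, chi2 = chi2, fisher_p = fp)
  }
  data.table::rbindlist(out)
}

#' Compare positive-gene sets between two time points
#'
#' Proportions, over the union of genes positive at either time point,
#' of genes positive only at the first, at both, or only at the second
#' (the stacked-bar comparison of serum-induction time points).
#'
#' @param calls_a,calls_b [call_genes()] tables for the same factor at
#'   the two time points.
#' @return data.table(only_a, both, only_b, n_union); proportions are NA
#'   with a warning when the union is empty.
#' @export
compare_timepoints <- function(calls_a, calls_b) {
  pa <- calls_a$gene_id[calls_a$positive]
  pb <- calls_b$gene_id[calls_b$positive]
  u <- union(pa, pb)
  if (length(u) == 0) {
    warning("no positive gene at either time point; proportions undefined")
    return(data.table::data.table(only_a = NA_real_, both = NA_real_,
                                  only_b = NA_real_, n_union = 0L))
  }
  both <- length(intersect(pa, pb))
  data.table::data.table(only_a = (length(pa) - both) / length(u),
                         both = both / length(u),
                         only_b = (length(pb) - both) / length(u),
                         n_union = length(u))
}
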