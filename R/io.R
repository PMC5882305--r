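#' Write a table as TSV
#'
#' @param dt data.frame/data.table.
#' @param path output file.
#' @export
write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a TSV table
#'
#' CRLF line endings are accepted and normalized.
#'
#' @param path input file.
#' @param required optional character vector of required column names.
#' @return data.table.
#' @export
read_tsv <- function(path, required = NULL) {
  dt <- data.table::fread(path, sep = "\t")
  if (!is.null(required) && !all(required %in% names(dt)))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(setdiff(required, names(dt)), collapse = ", ")))
  dt
}

#' Write promoter annotation as 6-column BED
#'
#' One record per gene covering the promoter window
#' `[tss - window/2, tss + window/2)`, 0-based half-open, with
#' name = gene_id, score = 0 and the gene strand.
#'
#' @param annotation a `chip_annotation`.
#' @param path output file.
#' @export
write_bed <- function(annotation, path) {
  stopifnot(inherits(annotation, "chip_annotation"))
  g <- annotation$genes
  half <- annotation$window_bp / 2
  bed <- data.table::data.table(chrom = g$chrom,
                                start = as.integer(pmax(g$tss - half, 0)),
                                end = as.integer(g$tss + half),
                                name = g$gene_id, score = 0L,
                                strand = g$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED file
#'
#' Validates 0-based half-open coordinates (start < end, start >= 0) and
#' strand values, reporting the offending line number.
#'
#' @param path input file.
#' @return data.table(chrom, start, end, name, score, strand).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 6) stop(sprintf("%s: expected 6 BED columns", path))
  data.table::setnames(dt, 1:6, c("chrom", "start", "end", "name",
                                  "score", "strand"))
  bad <- which(!(dt$start >= 0 & dt$end > dt$start))
  if (length(bad))
    stop(sprintf("%s: malformed interval at line %d (need 0 <= start < end)",
                 path, bad[1]))
  bads <- which(!dt$strand %in% c("+", "-"))
  if (length(bads))
    stop(sprintf("%s: invalid strand at line %d", path, bads[1]))
  dt[, 1:6]
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  x <- Biostrings::BStringSet(seqs)      # BString preserves soft-mask case
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA sequences
#'
#' @param path input file.
#' @return named character vector (case preserved).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(x))) stop(sprintf("%s: duplicate FASTA ids", path))
  stats::setNames(as.character(x), names(x))
}

#' Write a position frequency matrix (JASPAR-style 4-row counts)
#'
#' @param counts 4 x width matrix, rows A, C, G, T.
#' @param name motif name for the header line.
#' @param path output file.
#' @export
write_pfm <- function(counts, name, path) {
  stopifnot(nrow(counts) == 4)
  lines <- c(paste0(">", name),
             vapply(1:4, function(i)
               sprintf("%s  [ %s ]", c("A", "C", "G", "T")[i],
                       paste(counts[i, ], collapse = " ")), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a position frequency matrix (JASPAR-style 4-row counts)
#'
#' @param path input file.
#' @return list(name, counts) with a 4 x width count matrix.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!startsWith(lines[1], ">")) stop(sprintf("%s: missing '>' header", path))
  name <- sub("^>\\s*", "", lines[1])
  if (length(lines) < 5) stop(sprintf("%s: expected 4 matrix rows", path))
  rows <- lapply(lines[2:5], function(l) {
    nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1]]
    as.numeric(nums)
  })
  if (length(unique(lengths(rows))) != 1)
    stop(sprintf("%s: ragged matrix rows", path))
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  list(name = name, counts = counts)
}

#' Write an R object as JSON
#'
#' @param x object (lists/vectors).
#' @param path output file.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
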