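#' Write a sparse matrix in MatrixMarket triplet form
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` into `dir`.
#'
#' @param m Feature-by-cell matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_mtx <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(as_dgc(m), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a matrix written by [write_mtx()]
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return A sparse matrix with dimnames restored.
#' @export
read_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  as_dgc(m)
}

#' Write genomic intervals as BED (0-based, half-open)
#'
#' @param peaks Tibble with chrom, start, end (and optionally a name column).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_bed <- function(peaks, path) {
  cols <- intersect(c("chrom", "start", "end", "peak"), names(peaks))
  utils::write.table(peaks[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a peak tibble
#'
#' @param path BED file (3+ columns; 0-based half-open).
#' @return A tibble (chrom, start, end\[, peak\]).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "peak"
  tibble::as_tibble(df[, seq_len(min(4, ncol(df)))])
}

#' Write a result table as TSV
#'
#' @param x Data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_tsv_result <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
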