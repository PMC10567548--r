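# File I/O: FASTQ, MatrixMarket count directories, long-form tables.

# Read a (possibly gzipped) FASTQ into data.frame(id, seq).  Uses Biostrings
# for the parsing; read ids are truncated at the first whitespace.
.read_fastq <- function(path) {
  if (!file.exists(path)) .stopf("FASTQ file not found: %s", path)
  ds <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = FALSE),
    error = function(e) .stopf("failed to parse FASTQ %s: %s",
                               path, conditionMessage(e)))
  data.frame(id = sub("[ \t].*$", "", names(ds)),
             seq = as.character(ds),
             stringsAsFactors = FALSE)
}

# Write a 4-line-record gzipped FASTQ with constant quality.
.write_fastq_gz <- function(ids, seqs, path, qual_char = "I") {
  con <- gzfile(path, open = "wb")
  on.exit(close(con))
  if (length(ids)) {
    qual <- vapply(nchar(seqs), function(l) strrep(qual_char, l), "")
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con, sep = "\n")
  }
  invisible(path)
}

#' Write a spatial count matrix as a MatrixMarket directory
#'
#' Emits `matrix.mtx` (coordinate integer, features x pixels), `features.tsv`,
#' `pixels.tsv` (label, row, col) and `long.tsv` (row, col, feature, count) —
#' the long form lists each spatial location together with its expression
#' level.
#'
#' @param m A `spatial_counts` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_dir <- function(m, dir) {
  stopifnot(inherits(m, "spatial_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- file.path(dir, ".matrix.mtx.tmp")
  Matrix::writeMM(m$counts, tmp)
  file.rename(tmp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "features.tsv"))
  utils::write.table(m$pixels, file.path(dir, "pixels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tri <- methods::as(m$counts, "TsparseMatrix")
  long <- data.frame(row = m$pixels$row[tri@j + 1L],
                     col = m$pixels$col[tri@j + 1L],
                     feature = rownames(m$counts)[tri@i + 1L],
                     count = tri@x)
  long <- long[order(long$row, long$col, long$feature), , drop = FALSE]
  utils::write.table(long, file.path(dir, "long.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a spatial count matrix written by [write_counts_dir()]
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`, `pixels.tsv`.
#' @param modality `"RNA"` or `"protein"`.
#' @return A `spatial_counts` object.
#' @export
read_counts_dir <- function(dir, modality = c("RNA", "protein")) {
  modality <- match.arg(modality)
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  features <- readLines(file.path(dir, "features.tsv"))
  pixels <- utils::read.delim(file.path(dir, "pixels.tsv"),
                              stringsAsFactors = FALSE)
  dimnames(counts) <- list(features, pixels$label)
  new_spatial_counts(counts, modality, pixels)
}
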