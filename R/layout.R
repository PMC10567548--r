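# Read-2 layout: where the UMI, spatial barcodes and ligation linker sit.

# Default 30-nt ligation linker joining barcode B to barcode A.
DEFAULT_LINKER <- "GTGGCCGATGTTTCGCATCGGCGTACGACT"

#' Describe the segment layout of the barcode read (Read 2)
#'
#' Read 2 of both libraries carries, in order, the molecule UMI, the column
#' (B) spatial barcode, the ligation linker, and the row (A) spatial barcode.
#' Offsets are 0-based byte positions within the read; segments must not
#' overlap.  `r1_tag` locates the ADT tag within Read 1 of the protein
#' library.
#'
#' @param umi,bcB,bcA Integer pairs `c(offset, length)` for the UMI and the
#'   column/row spatial barcodes within Read 2.
#' @param linker Integer pair `c(offset, length)` for the ligation linker.
#' @param linker_seq Expected linker sequence; its nchar must equal the linker
#'   length.
#' @param r1_tag Integer pair `c(offset, length)`: position of the ADT tag
#'   sequence within Read 1 of the ADT library.
#' @param read2_length Total Read-2 length the layout expects; the parsed span
#'   must fit inside it.
#' @return A `read_layout` object.
#' @examples
#' read_layout()
#' @export
read_layout <- function(umi = c(0L, 10L),
                        bcB = c(10L, 8L),
                        linker = c(18L, 30L),
                        bcA = c(48L, 8L),
                        linker_seq = DEFAULT_LINKER,
                        r1_tag = c(0L, 15L),
                        read2_length = NULL) {
  segs <- list(umi = umi, bcB = bcB, linker = linker, bcA = bcA)
  for (nm in names(segs)) {
    s <- segs[[nm]]
    if (length(s) != 2L || any(s < 0L) || s[2L] < 1L)
      .stopf("layout segment '%s' must be c(offset >= 0, length >= 1)", nm)
  }
  if (nchar(linker_seq) != linker[2L])
    .stopf("linker_seq has %d nt but the linker segment length is %d",
           nchar(linker_seq), linker[2L])
  if (!.is_dna(linker_seq)) .stopf("linker_seq contains non-ACGT characters")
  # overlap check on [offset, offset+length)
  iv <- t(vapply(segs, function(s) c(s[1L], s[1L] + s[2L]), numeric(2)))
  ord <- order(iv[, 1L])
  iv <- iv[ord, , drop = FALSE]
  if (any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
    .stopf("layout segments overlap")
  span <- as.integer(max(iv[, 2L]))
  if (is.null(read2_length)) read2_length <- span
  if (span > read2_length)
    .stopf("layout span (%d) exceeds read2_length (%d)", span, read2_length)
  if (length(r1_tag) != 2L || any(r1_tag < 0L) || r1_tag[2L] < 1L)
    .stopf("r1_tag must be c(offset >= 0, length >= 1)")
  structure(
    list(umi = as.integer(umi), bcB = as.integer(bcB),
         linker = as.integer(linker), bcA = as.integer(bcA),
         linker_seq = linker_seq, r1_tag = as.integer(r1_tag),
         read2_length = as.integer(read2_length), span = span),
    class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  cat("Read-2 layout (0-based offsets):\n")
  for (nm in c("umi", "bcB", "linker", "bcA"))
    cat(sprintf("  %-6s offset %2d length %2d\n", nm, x[[nm]][1L], x[[nm]][2L]))
  cat(sprintf("  linker sequence: %s\n", x$linker_seq))
  cat(sprintf("  span %d nt within read length %d\n", x$span, x$read2_length))
  cat(sprintf("  Read-1 ADT tag: offset %d length %d\n",
              x$r1_tag[1L], x$r1_tag[2L]))
  invisible(x)
}

# 1-based substring bounds for a layout segment.
.seg_bounds <- function(layout, nm) {
  s <- layout[[nm]]
  c(s[1L] + 1L, s[1L] + s[2L])
}
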