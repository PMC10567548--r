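# Demultiplexing: Read-2 parsing, whitelist error correction, pixel
# assignment.  Gates are applied in a fixed order (linker, then barcode A,
# then barcode B) and each read is counted once, at its first failure.

#' Slice Read 2 into its layout segments
#'
#' Pure slicing by layout offsets; no error correction.  Vectorized over
#' reads.
#'
#' @param seq Character vector of Read-2 sequences, each at least as long as
#'   the layout span.
#' @param layout A [read_layout()].
#' @return data.frame with columns `umi`, `bcB`, `linker`, `bcA`.
#' @export
parse_read2 <- function(seq, layout) {
  stopifnot(inherits(layout, "read_layout"))
  short <- nchar(seq) < layout$span
  if (any(short))
    .stopf("read %d is shorter (%d nt) than the layout span (%d nt)",
           which(short)[1L], nchar(seq[which(short)[1L]]), layout$span)
  slice <- function(nm) {
    b <- .seg_bounds(layout, nm)
    substr(seq, b[1L], b[2L])
  }
  data.frame(umi = slice("umi"), bcB = slice("bcB"),
             linker = slice("linker"), bcA = slice("bcA"),
             stringsAsFactors = FALSE)
}

# Vectorized whitelist matching.
# Returns list(index = integer (NA when not uniquely matched),
#              status = "exact"|"corrected"|"ambiguous"|"nomatch").
.match_barcodes <- function(seqs, wl, max_hamming) {
  n <- length(seqs)
  bad_len <- nchar(seqs) != attr(wl, "bc_length")
  if (any(bad_len))
    .stopf("barcode query length %d does not match whitelist length %d",
           nchar(seqs[which(bad_len)[1L]]), attr(wl, "bc_length"))
  idx <- match(seqs, wl$seq)
  status <- ifelse(is.na(idx), "nomatch", "exact")
  todo <- which(is.na(idx))
  if (max_hamming > 0L && length(todo)) {
    qmat <- .seq_char_matrix(seqs[todo])
    m <- length(todo)
    best <- rep(Inf, m); second <- rep(Inf, m); best_idx <- rep(NA_integer_, m)
    wl_chars <- .seq_char_matrix(wl$seq)
    for (j in seq_len(nrow(wl))) {
      d <- rowSums(qmat != matrix(wl_chars[j, ], nrow = m,
                                  ncol = ncol(qmat), byrow = TRUE))
      better <- d < best
      second[better] <- best[better]
      best_idx[better] <- j
      best[better] <- d[better]
      tie <- !better & d < second
      second[tie] <- d[tie]
    }
    hit <- best <= max_hamming & second > best
    amb <- best <= max_hamming & second == best
    idx[todo[hit]] <- best_idx[hit]
    status[todo[hit]] <- "corrected"
    status[todo[amb]] <- "ambiguous"
  }
  list(index = idx, status = status)
}

#' Error-correct a barcode against a whitelist
#'
#' Returns the unique whitelist index within Hamming distance `max_hamming`
#' of the query.  An exact match always wins; if two or more whitelist
#' entries sit at the same minimal distance `<= max_hamming`, the call is
#' ambiguous and no index is returned (ambiguous reads are dropped rather
#' than arbitrarily resolved, since a wrong pixel assignment is spatial
#' cross-contamination).
#'
#' @param seq Character vector of barcode sequences (same length as the
#'   whitelist barcodes).
#' @param wl A [barcode_whitelist()].
#' @param max_hamming Maximum correction distance.
#' @return Integer vector of whitelist indices, `NA` where there is no unique
#'   match; attribute `"status"` holds `"exact"`, `"corrected"`,
#'   `"ambiguous"` or `"nomatch"` per query.
#' @examples
#' wl <- barcode_whitelist(c("AACCGGTT", "TTGGCCAA"), axis = "A")
#' correct_barcode("AACCGGTA", wl, max_hamming = 1)
#' @export
correct_barcode <- function(seq, wl, max_hamming = 1L) {
  res <- .match_barcodes(seq, wl, max_hamming)
  structure(res$index, status = res$status)
}

.new_demux_stats <- function(total, short_read, fail_linker, fail_bcA,
                             fail_bcB, ambiguous, passed) {
  structure(list(total = total, short_read = short_read,
                 fail_linker = fail_linker, fail_bcA = fail_bcA,
                 fail_bcB = fail_bcB, ambiguous = ambiguous, passed = passed),
            class = "demux_stats")
}

#' @export
print.demux_stats <- function(x, ...) {
  cat(sprintf(paste0("Demux: %d reads -> %d passed ",
                     "(short %d, linker %d, bcA %d, bcB %d, ambiguous %d)\n"),
              x$total, x$passed, x$short_read, x$fail_linker,
              x$fail_bcA, x$fail_bcB, x$ambiguous))
  invisible(x)
}

#' Demultiplex a paired-end library into pixel-addressed records
#'
#' For every read pair: parse Read 2 by the layout; gate on the ligation
#' linker (Hamming distance to the expected sequence `<= max_hamming_linker`);
#' error-correct barcode A then barcode B against their whitelists; emit a
#' record with the pixel address (row = A index, col = B index), the UMI and
#' the Read-1 payload.  Gates apply in that order and each read is counted
#' once, at its first failure; reads shorter than the layout span are counted
#' as `short_read`.  If a whitelist was flagged unsafe for the correction
#' radius, matching for that axis falls back to exact.
#'
#' @param r1_path,r2_path Paths to the paired FASTQ files (may be gzipped).
#'   Read ids must agree pairwise.
#' @param layout A [read_layout()].
#' @param wlA,wlB Whitelists for axes A (rows) and B (columns).
#' @param max_hamming_bc Barcode correction radius (default 1).
#' @param max_hamming_linker Allowed linker mismatches (default 2).
#' @param modality `"RNA"` or `"protein"`; carried into the records.
#' @return List with `records` (data.frame: read_id, row, col, umi, payload,
#'   modality) and `stats` (a `demux_stats`; components sum to the total).
#' @export
demux_library <- function(r1_path, r2_path, layout, wlA, wlB,
                          max_hamming_bc = 1L, max_hamming_linker = 2L,
                          modality = c("RNA", "protein")) {
  modality <- match.arg(modality)
  stopifnot(inherits(layout, "read_layout"),
            inherits(wlA, "barcode_whitelist"),
            inherits(wlB, "barcode_whitelist"))
  r1 <- .read_fastq(r1_path)
  r2 <- .read_fastq(r2_path)
  if (nrow(r1) != nrow(r2))
    .stopf("R1 has %d records but R2 has %d", nrow(r1), nrow(r2))
  mism <- which(r1$id != r2$id)
  if (length(mism))
    .stopf("R1/R2 read ids disagree at record %d ('%s' vs '%s')",
           mism[1L], r1$id[mism[1L]], r2$id[mism[1L]])
  n <- nrow(r2)

  mh_A <- if (attr(wlA, "correction_safe")) max_hamming_bc else 0L
  mh_B <- if (attr(wlB, "correction_safe")) max_hamming_bc else 0L
  if (mh_A < max_hamming_bc || mh_B < max_hamming_bc)
    .warnf("unsafe correction radius for whitelist min distance: using exact matching")

  empty <- data.frame(read_id = character(0), row = integer(0),
                      col = integer(0), umi = character(0),
                      payload = character(0), modality = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(records = empty,
                stats = .new_demux_stats(0L, 0L, 0L, 0L, 0L, 0L, 0L)))

  short <- nchar(r2$seq) < layout$span
  ok <- which(!short)
  n_short <- sum(short)
  if (!length(ok)) {
    return(list(records = empty,
                stats = .new_demux_stats(n, n_short, 0L, 0L, 0L, 0L, 0L)))
  }
  parts <- parse_read2(r2$seq[ok], layout)

  exp_chars <- strsplit(layout$linker_seq, "", fixed = TRUE)[[1L]]
  lmat <- .seq_char_matrix(parts$linker)
  ldist <- rowSums(lmat != matrix(exp_chars, nrow = nrow(lmat),
                                  ncol = length(exp_chars), byrow = TRUE))
  linker_ok <- ldist <= max_hamming_linker
  n_fail_linker <- sum(!linker_ok)

  state <- rep("pending", length(ok))
  state[!linker_ok] <- "fail_linker"
  live <- which(linker_ok)

  rowA <- rep(NA_integer_, length(ok))
  colB <- rep(NA_integer_, length(ok))
  n_fail_A <- 0L; n_fail_B <- 0L; n_amb <- 0L
  if (length(live)) {
    mA <- .match_barcodes(parts$bcA[live], wlA, mh_A)
    ambA <- mA$status == "ambiguous"
    failA <- is.na(mA$index) & !ambA
    n_fail_A <- sum(failA); n_amb <- n_amb + sum(ambA)
    state[live[failA]] <- "fail_bcA"
    state[live[ambA]] <- "ambiguous"
    liveB <- live[!failA & !ambA]
    rowA[liveB] <- mA$index[!failA & !ambA]
    if (length(liveB)) {
      mB <- .match_barcodes(parts$bcB[liveB], wlB, mh_B)
      ambB <- mB$status == "ambiguous"
      failB <- is.na(mB$index) & !ambB
      n_fail_B <- sum(failB); n_amb <- n_amb + sum(ambB)
      state[liveB[failB]] <- "fail_bcB"
      state[liveB[ambB]] <- "ambiguous"
      pass <- liveB[!failB & !ambB]
      colB[pass] <- mB$index[!failB & !ambB]
      state[pass] <- "passed"
    }
  }

  keep <- which(state == "passed")
  records <- data.frame(read_id = r2$id[ok][keep],
                        row = rowA[keep], col = colB[keep],
                        umi = parts$umi[keep],
                        payload = r1$seq[ok][keep],
                        modality = rep(modality, length(keep)),
                        stringsAsFactors = FALSE)
  stats <- .new_demux_stats(n, n_short, n_fail_linker, n_fail_A, n_fail_B,
                            n_amb, length(keep))
  stopifnot(stats$total == stats$short_read + stats$fail_linker +
              stats$fail_bcA + stats$fail_bcB + stats$ambiguous + stats$passed)
  list(records = records, stats = stats)
}
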