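# Spatial barcode whitelists: one per axis (A = rows, B = columns).

#' Construct a spatial barcode whitelist
#'
#' A whitelist is the ordered set of barcode sequences for one axis of the
#' pixel grid: axis A indexes rows (A1..AN), axis B indexes columns.  The
#' minimum pairwise Hamming distance is computed on construction; it bounds
#' the safe error-correction radius (correction within Hamming `h` is
#' unambiguous only when `2*h <` the minimum pairwise distance).
#'
#' @param seqs Character vector of equal-length A/C/G/T barcode sequences, in
#'   index order (entry i is barcode i).
#' @param axis `"A"` (rows) or `"B"` (columns).
#' @param max_hamming Correction radius the whitelist is intended for; if the
#'   radius is unsafe for the observed minimum pairwise distance a warning is
#'   issued and [demux_library()] will fall back to exact matching.
#' @return A `barcode_whitelist`: data.frame with columns `index`, `seq` plus
#'   attributes `axis`, `bc_length`, `min_dist`, `correction_safe`.
#' @export
barcode_whitelist <- function(seqs, axis = c("A", "B"), max_hamming = 1L) {
  axis <- match.arg(axis)
  seqs <- as.character(seqs)
  if (length(seqs) < 1L) .stopf("whitelist %s is empty", axis)
  bad <- which(!.is_dna(seqs))
  if (length(bad))
    .stopf("whitelist %s: non-ACGT sequence at index %d", axis, bad[1L])
  if (length(unique(nchar(seqs))) != 1L)
    .stopf("whitelist %s: barcodes have mixed lengths", axis)
  if (anyDuplicated(seqs))
    .stopf("whitelist %s: duplicate barcode sequence '%s'",
           axis, seqs[duplicated(seqs)][1L])
  min_dist <- .min_pairwise_hamming(seqs)
  safe <- is.na(min_dist) || 2L * max_hamming < min_dist
  if (!safe)
    .warnf(paste0("whitelist %s: correction radius %d is unsafe for minimum ",
                  "pairwise distance %d (need 2*max_hamming < min_dist); ",
                  "demultiplexing will fall back to exact matching"),
           axis, max_hamming, min_dist)
  structure(
    data.frame(index = seq_along(seqs), seq = seqs,
               stringsAsFactors = FALSE),
    axis = axis, bc_length = nchar(seqs[1L]),
    min_dist = min_dist, correction_safe = safe,
    class = c("barcode_whitelist", "data.frame"))
}

#' Load a barcode whitelist from a TSV file
#'
#' The file has two whitespace-separated columns, `index` and `seq`, with no
#' header required; lines starting with `#` are comments.  Indices must be
#' contiguous 1..N.
#'
#' @param path Path to the whitelist file.
#' @inheritParams barcode_whitelist
#' @return A `barcode_whitelist`.
#' @export
load_whitelist <- function(path, axis = c("A", "B"), max_hamming = 1L) {
  axis <- match.arg(axis)
  if (!file.exists(path)) .stopf("whitelist file not found: %s", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^index\\b", lines[1L], ignore.case = TRUE))
    lines <- lines[-1L]
  if (!length(lines)) .stopf("whitelist file is empty: %s", path)
  parts <- strsplit(lines, "[\t ]+")
  if (any(lengths(parts) < 2L))
    .stopf("%s: malformed whitelist line: '%s'",
           path, lines[lengths(parts) < 2L][1L])
  idx <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  seqs <- toupper(vapply(parts, `[`, "", 2L))
  if (anyNA(idx)) .stopf("%s: non-integer index on line '%s'",
                         path, lines[which(is.na(idx))[1L]])
  ord <- order(idx)
  idx <- idx[ord]; seqs <- seqs[ord]
  if (!identical(idx, seq_along(idx)))
    .stopf("%s: indices are not contiguous 1..N (saw %s)",
           path, paste(utils::head(idx, 5L), collapse = ","))
  barcode_whitelist(seqs, axis = axis, max_hamming = max_hamming)
}

#' Write a whitelist as index/seq TSV
#'
#' @param wl A `barcode_whitelist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_whitelist <- function(wl, path) {
  stopifnot(inherits(wl, "barcode_whitelist"))
  writeLines(sprintf("%d\t%s", wl$index, wl$seq), path)
  invisible(path)
}

#' @export
print.barcode_whitelist <- function(x, ...) {
  cat(sprintf("Barcode whitelist, axis %s: %d barcodes of %d nt, min pairwise Hamming %s\n",
              attr(x, "axis"), nrow(x), attr(x, "bc_length"),
              as.character(attr(x, "min_dist"))))
  invisible(x)
}

#' Generate a pair of synthetic barcode whitelists
#'
#' Greedy rejection sampling of random codes: a candidate is kept only if it
#' is at Hamming distance `>= min_dist` from every code already accepted
#' (across both axes, so the A and B sets are disjoint).  Deterministic for a
#' given seed.
#'
#' @param n Barcodes per axis.
#' @param length Barcode length in nt.
#' @param min_dist Required minimum pairwise Hamming distance.
#' @param seed Integer RNG seed.
#' @param max_tries Candidate draws before declaring the combination
#'   infeasible.
#' @return List with elements `A` and `B`, each a `barcode_whitelist`.
#' @export
generate_fixture_whitelists <- function(n, length = 8L, min_dist = 3L,
                                        seed = 1L, max_tries = 2000L * n) {
  if (min_dist > length)
    .stopf("infeasible: min_dist %d exceeds barcode length %d", min_dist, length)
  .with_seed(seed, {
    accepted <- character(0)
    acc_mat <- NULL
    tries <- 0L
    while (length(accepted) < 2L * n) {
      tries <- tries + 1L
      if (tries > max_tries)
        .stopf("infeasible (n=%d, length=%d, min_dist=%d): gave up after %d draws",
               n, length, min_dist, max_tries)
      cand <- .rand_dna(1L, length)
      cand_chars <- strsplit(cand, "", fixed = TRUE)[[1L]]
      if (!is.null(acc_mat)) {
        d <- rowSums(acc_mat != matrix(cand_chars, nrow = nrow(acc_mat),
                                       ncol = length, byrow = TRUE))
        if (min(d) < min_dist) next
      }
      accepted <- c(accepted, cand)
      acc_mat <- rbind(acc_mat, cand_chars)
    }
    list(A = barcode_whitelist(accepted[seq_len(n)], axis = "A"),
         B = barcode_whitelist(accepted[n + seq_len(n)], axis = "B"))
  })
}
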