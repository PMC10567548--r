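# Shared low-level helpers: DNA string handling, Hamming distances, seeded RNG.

DNA_BASES <- c("A", "C", "G", "T")

#' Hamming distance between two equal-length strings
#'
#' @param a,b Character scalars of equal nchar.
#' @return Integer number of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): strings differ in length")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Character matrix (n x len) from equal-length DNA strings.
.seq_char_matrix <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(character(0), nrow = 0))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences must all have the same length")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = len, byrow = TRUE)
}

# TRUE where string contains only A/C/G/T.
.is_dna <- function(seqs) {
  !grepl("[^ACGT]", seqs)
}

# n random DNA strings of length len (uses current RNG state).
.rand_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Apply uniform per-base substitutions (always to a different base).
.mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    # draw one of the three alternative bases per hit position
    alt <- vapply(flat[hit], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    flat[hit] <- alt
  }
  idx <- rep.int(seq_along(seqs), lens)
  vapply(split(flat, idx), paste, "", collapse = "")
}

# Evaluate expr under a temporary RNG seed, restoring global RNG state after.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Minimum pairwise Hamming distance within a set of equal-length strings.
.min_pairwise_hamming <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(NA_integer_)
  m <- .seq_char_matrix(seqs)
  best <- nchar(seqs[1L])
  for (i in seq_len(n - 1L)) {
    d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                   matrix(m[i, ], nrow = n - i, ncol = ncol(m), byrow = TRUE))
    best <- min(best, d)
    if (best == 0L) break
  }
  as.integer(best)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
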