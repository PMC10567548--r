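# Quantification: payload -> feature assignment, UMI collapse, and the
# spatial count matrices.

#' Match an ADT read payload to a panel antibody
#'
#' Slices the tag region out of the Read-1 payload and finds the unique panel
#' tag within Hamming distance `max_hamming`; exact matches always win and
#' ties yield no match.  Vectorized over payloads.
#'
#' @param payload Character vector of Read-1 sequences.
#' @param panel An [adt_panel()].
#' @param max_hamming Maximum tag correction distance (default 1).
#' @param r1_tag Integer pair `c(offset, length)` locating the tag in the
#'   payload; defaults to the panel tag length at offset 0.
#' @return Character vector of antibody ids, `NA` where unmatched.
#' @export
match_adt_tag <- function(payload, panel, max_hamming = 1L, r1_tag = NULL) {
  stopifnot(inherits(panel, "adt_panel"))
  tl <- attr(panel, "tag_length")
  if (is.null(r1_tag)) r1_tag <- c(0L, tl)
  if (r1_tag[2L] != tl)
    .stopf("r1_tag length (%d) does not match panel tag length (%d)",
           r1_tag[2L], tl)
  short <- nchar(payload) < r1_tag[1L] + r1_tag[2L]
  if (any(short))
    .stopf("payload %d is too short for the tag region", which(short)[1L])
  tag <- substr(payload, r1_tag[1L] + 1L, r1_tag[1L] + r1_tag[2L])
  # reuse the whitelist matcher over the panel tags
  pseudo_wl <- structure(data.frame(index = seq_len(nrow(panel)),
                                    seq = panel$tag_seq,
                                    stringsAsFactors = FALSE),
                         bc_length = tl)
  res <- .match_barcodes(tag, pseudo_wl, max_hamming)
  out <- panel$antibody_id[res$index]
  out
}

#' Build a k-mer index over a toy transcriptome
#'
#' Maps every k-mer of every transcript to the gene(s) containing it; the
#' index backs the exact-match toy assigner used on synthetic data (real
#' genome alignment is delegated to an external aligner, whose output can be
#' consumed via [load_external_assignments()]).
#'
#' @param transcriptome FASTA path or named sequence vector.
#' @param k k-mer length (default 31).
#' @return A `kmer_index` list with the k-mer table and `k`.
#' @export
build_kmer_index <- function(transcriptome, k = 31L) {
  tx <- .as_transcriptome(transcriptome)
  if (any(nchar(tx) < k))
    .warnf("%d transcript(s) shorter than k=%d are unindexable",
           sum(nchar(tx) < k), k)
  pieces <- lapply(names(tx), function(g) {
    s <- tx[[g]]
    n <- nchar(s) - k + 1L
    if (n < 1L) return(NULL)
    data.frame(kmer = unique(substring(s, seq_len(n), seq_len(n) + k - 1L)),
               gene = g, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, pieces)
  if (is.null(map)) .stopf("no transcript is long enough for k=%d", k)
  # unique kmer table with gene multiplicity
  ukmer <- unique(map$kmer)
  map$kid <- match(map$kmer, ukmer)
  structure(list(k = as.integer(k), kmers = ukmer,
                 map = map[, c("kid", "gene")],
                 genes = names(tx)),
            class = "kmer_index")
}

#' Assign RNA payloads to genes by exact k-mer lookup
#'
#' All k-mers of the payload are looked up in the index; if they hit exactly
#' one gene the read is assigned to it, otherwise (no hit, or hits in two or
#' more genes) there is no match.  Payloads shorter than k never match.
#'
#' @param payload Character vector of Read-1 sequences.
#' @param index A [build_kmer_index()] result.
#' @return Character vector of gene ids, `NA` where unassigned.
#' @export
assign_transcript_toy <- function(payload, index) {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  n <- length(payload)
  out <- rep(NA_character_, n)
  lens <- nchar(payload)
  usable <- which(lens >= k)
  if (!length(usable)) return(out)
  nk <- lens[usable] - k + 1L
  read_of <- rep.int(usable, nk)
  starts <- unlist(lapply(nk, seq_len), use.names = FALSE)
  kmers <- substring(payload[read_of], starts, starts + k - 1L)
  kid <- match(kmers, index$kmers)
  ok <- !is.na(kid)
  if (!any(ok)) return(out)
  hits <- data.frame(read = read_of[ok], kid = kid[ok])
  hits <- unique(hits)
  hits <- merge(hits, index$map, by = "kid")
  pg <- unique(hits[, c("read", "gene")])
  ng <- table(pg$read)
  uniq_reads <- as.integer(names(ng)[ng == 1L])
  if (length(uniq_reads)) {
    pg1 <- pg[pg$read %in% uniq_reads, , drop = FALSE]
    out[pg1$read] <- pg1$gene
  }
  out
}

#' Read externally produced read-to-gene assignments
#'
#' Pluggable interface for real alignment: a two-column TSV (`read_id`,
#' `gene`) produced by an external aligner replaces the toy assigner.
#'
#' @param path TSV path with header columns `read_id` and `gene`.
#' @return data.frame with columns `read_id`, `gene`.
#' @export
load_external_assignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("read_id", "gene") %in% names(df)))
    .stopf("%s must have columns read_id, gene", path)
  df[, c("read_id", "gene")]
}

# Directional single-mismatch UMI clustering within one (pixel, feature)
# group.  umis/counts: per-distinct-UMI read counts.  Returns the number of
# cluster roots (the standard directional rule: an edge u -> v exists when
# Hamming(u, v) == 1 and count(u) >= 2*count(v) - 1; nodes are absorbed
# transitively, visiting putative roots in decreasing count order).
.directional_roots <- function(umis, counts) {
  m <- length(umis)
  if (m == 1L) return(1L)
  ord <- order(-counts, umis)
  umis <- umis[ord]; counts <- counts[ord]
  cm <- .seq_char_matrix(umis)
  dist1 <- function(i, j) sum(cm[i, ] != cm[j, ]) == 1L
  assigned <- rep(FALSE, m)
  roots <- 0L
  for (i in seq_len(m)) {
    if (assigned[i]) next
    roots <- roots + 1L
    assigned[i] <- TRUE
    queue <- i
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in seq_len(m)) {
        if (assigned[v]) next
        if (dist1(u, v) && counts[u] >= 2L * counts[v] - 1L) {
          assigned[v] <- TRUE
          queue <- c(queue, v)
        }
      }
    }
  }
  roots
}

#' Collapse UMIs into molecule counts per pixel and feature
#'
#' In `exact` mode the count is the number of distinct UMI sequences per
#' (pixel, feature) — the default, matching standard ADT counting tools.  In
#' `directional1mm` mode UMIs within Hamming distance 1 are merged under the
#' directional rule (a UMI absorbs a neighbour seen at most
#' `(count + 1) / 2` times), and network roots are counted.
#'
#' @param records data.frame with columns `row`, `col`, `feature`, `umi` (one
#'   row per read).
#' @param mode `"exact"` or `"directional1mm"`.
#' @return data.frame with columns `row`, `col`, `feature`, `count`.
#' @export
collapse_umis <- function(records, mode = c("exact", "directional1mm")) {
  mode <- match.arg(mode)
  need <- c("row", "col", "feature", "umi")
  if (!all(need %in% names(records)))
    .stopf("records must have columns %s", paste(need, collapse = ", "))
  if (!nrow(records))
    return(data.frame(row = integer(0), col = integer(0),
                      feature = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  if (mode == "exact") {
    u <- unique(records[, need])
    agg <- stats::aggregate(list(count = rep(1L, nrow(u))),
                            u[, c("row", "col", "feature")], sum)
  } else {
    # per-(pixel, feature, umi) read counts, then directional clustering
    key <- paste(records$row, records$col, records$feature, sep = "\r")
    tab <- stats::aggregate(list(n = rep(1L, nrow(records))),
                            list(key = key, umi = records$umi), sum)
    groups <- split(tab, tab$key)
    counts <- vapply(groups, function(g) .directional_roots(g$umi, g$n), 0L)
    parts <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
    agg <- data.frame(row = as.integer(parts[, 1L]),
                      col = as.integer(parts[, 2L]),
                      feature = parts[, 3L], count = as.integer(counts),
                      stringsAsFactors = FALSE)
  }
  agg <- agg[order(agg$row, agg$col, agg$feature), , drop = FALSE]
  rownames(agg) <- NULL
  agg$count <- as.integer(agg$count)
  agg
}

# internal constructor
new_spatial_counts <- function(counts, modality, pixels) {
  structure(list(counts = counts, modality = modality, pixels = pixels),
            class = "spatial_counts")
}

#' Build a sparse spatial count matrix
#'
#' Features are rows, pixels are columns; pixels are labelled
#' `"{row}x{col}"` and ordered row-major.  Protein matrices keep all panel
#' features (all-zero rows included) so the panel size stays structurally
#' visible; RNA matrices by default contain only observed genes unless a full
#' `features` universe is supplied with `drop_unobserved = FALSE`.
#'
#' @param counts data.frame with columns `row`, `col`, `feature`, `count`.
#' @param modality `"RNA"` or `"protein"`.
#' @param features Feature universe in output order (for protein: the panel's
#'   antibody ids).  If `NULL`, the sorted observed features are used.
#' @param grid Integer pair `(n_rows, n_cols)`: the pixel grid; counts outside
#'   it are an error.
#' @param drop_unobserved Drop features with zero total count (default TRUE
#'   for RNA, FALSE for protein).
#' @param keep_pixels Optional character vector of pixel labels to retain
#'   (e.g. a tissue-coverage filter); default keeps every pixel with at least
#'   one count.
#' @return A `spatial_counts` object: sparse integer matrix plus a pixel
#'   table (label, row, col).
#' @export
build_matrix <- function(counts, modality = c("RNA", "protein"),
                         features = NULL, grid,
                         drop_unobserved = (modality == "RNA"),
                         keep_pixels = NULL) {
  modality <- match.arg(modality)
  force(drop_unobserved)
  if (!all(c("row", "col", "feature", "count") %in% names(counts)))
    .stopf("counts must have columns row, col, feature, count")
  if (any(counts$count < 0)) .stopf("negative counts")
  out_of_grid <- counts$row < 1L | counts$row > grid[1L] |
    counts$col < 1L | counts$col > grid[2L]
  if (any(out_of_grid))
    .stopf("pixel (%d,%d) is outside the %dx%d grid",
           counts$row[out_of_grid][1L], counts$col[out_of_grid][1L],
           grid[1L], grid[2L])
  if (is.null(features)) {
    features <- sort(unique(counts$feature))
  } else {
    unknown <- setdiff(counts$feature, features)
    if (length(unknown))
      .stopf("feature '%s' is not in the supplied feature universe", unknown[1L])
  }
  if (drop_unobserved && modality == "RNA")
    features <- features[features %in% counts$feature]
  label <- sprintf("%dx%d", counts$row, counts$col)
  px <- unique(data.frame(label = label, row = counts$row, col = counts$col,
                          stringsAsFactors = FALSE))
  if (!is.null(keep_pixels)) px <- px[px$label %in% keep_pixels, , drop = FALSE]
  px <- px[order(px$row, px$col), , drop = FALSE]
  rownames(px) <- NULL
  i <- match(counts$feature, features)
  j <- match(label, px$label)
  keep <- !is.na(j) & counts$count > 0L
  mat <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = counts$count[keep],
                              dims = c(length(features), nrow(px)),
                              dimnames = list(features, px$label))
  mat <- methods::as(mat, "CsparseMatrix")
  new_spatial_counts(mat, modality, px)
}

#' @export
print.spatial_counts <- function(x, ...) {
  cat(sprintf("Spatial %s counts: %d features x %d pixels, %d nonzero, total %d UMIs\n",
              x$modality, nrow(x$counts), ncol(x$counts),
              Matrix::nnzero(x$counts), as.integer(sum(x$counts))))
  invisible(x)
}

#' @export
dim.spatial_counts <- function(x) dim(x$counts)
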