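# Per-pixel QC, CLR / log normalization, signature scoring, pseudo-bulk.

#' Per-pixel quality metrics
#'
#' For every pixel: total UMI count (column sum) and feature count (features
#' detected with at least one UMI), plus matrix-wide means of both — the
#' per-pixel averages typically reported for this assay.
#'
#' @param m A `spatial_counts` object.
#' @return A `pixel_qc` list: `per_pixel` (data.frame pixel/row/col/
#'   umi_count/feature_count) and `summary` (mean_umi, mean_features,
#'   n_pixels).
#' @export
qc_metrics <- function(m) {
  stopifnot(inherits(m, "spatial_counts"))
  umi <- Matrix::colSums(m$counts)
  nf <- Matrix::colSums(m$counts > 0)
  per <- data.frame(pixel = m$pixels$label, row = m$pixels$row,
                    col = m$pixels$col,
                    umi_count = as.integer(umi),
                    feature_count = as.integer(nf),
                    stringsAsFactors = FALSE)
  structure(list(per_pixel = per,
                 summary = list(mean_umi = mean(umi),
                                mean_features = mean(nf),
                                n_pixels = ncol(m$counts),
                                modality = m$modality)),
            class = "pixel_qc")
}

#' @export
print.pixel_qc <- function(x, ...) {
  cat(sprintf("Pixel QC (%s): %d pixels, mean UMI/pixel %.1f, mean features/pixel %.1f\n",
              x$summary$modality, x$summary$n_pixels,
              x$summary$mean_umi, x$summary$mean_features))
  invisible(x)
}

.new_normalized <- function(values, modality, method, extra = list()) {
  structure(c(list(values = values, modality = modality, method = method),
              extra),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("Normalized %s matrix (%s): %d features x %d pixels\n",
              x$modality, x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Centred log-ratio (CLR) normalization
#'
#' The standard compositional transform for ADT counts:
#' `y = ln(x + 1) - mean(ln(x + 1))`, with the mean taken over all features
#' within a pixel (`per_pixel`, the default) or over all pixels within a
#' feature (`per_feature`).  Natural log; the +1 pseudocount handles zeros.
#' Under the default margin every pixel's values sum to zero.
#'
#' @param m A `spatial_counts` object.
#' @param margin `"per_pixel"` or `"per_feature"`.
#' @return A `normalized_matrix` (dense values, method `"CLR"`).
#' @examples
#' # a pixel with counts (3, 0, 0) maps to (0.9242, -0.4621, -0.4621)
#' @export
clr_normalize <- function(m, margin = c("per_pixel", "per_feature")) {
  margin <- match.arg(margin)
  stopifnot(inherits(m, "spatial_counts"))
  if (nrow(m$counts) == 0L || ncol(m$counts) == 0L)
    .stopf("cannot CLR-normalize an empty matrix")
  lx <- log1p(as.matrix(m$counts))
  y <- if (margin == "per_pixel") sweep(lx, 2L, colMeans(lx))
       else sweep(lx, 1L, rowMeans(lx))
  .new_normalized(y, m$modality, "CLR", list(margin = margin))
}

#' Library-size log-normalization for RNA counts
#'
#' `y = ln(1 + scale * x / colsum)`; all-zero pixels map to zeros.
#'
#' @param m A `spatial_counts` object.
#' @param scale Size factor target (default 10,000).
#' @return A `normalized_matrix` (method `"lognorm"`).
#' @export
lognorm_rna <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "spatial_counts"))
  if (scale <= 0) .stopf("scale must be positive")
  cs <- Matrix::colSums(m$counts)
  cs[cs == 0] <- 1  # all-zero pixels stay zero, no division error
  y <- log1p(sweep(as.matrix(m$counts), 2L, cs, "/") * scale)
  .new_normalized(y, m$modality, "lognorm", list(scale = scale))
}

#' Score pixels against a gene signature
#'
#' `mean_z`: each listed feature present in the matrix is z-scored across
#' pixels (zero-variance features are excluded), and a pixel's score is the
#' mean of those z-scores.  The score is invariant to gene-list order and to
#' duplicate entries (the list is deduplicated first); listed features absent
#' from the matrix are dropped with a warning.
#'
#' @param nm A `normalized_matrix`.
#' @param genes Character vector of feature ids (e.g. the Tph signature
#'   `tph_signature("RNA")`).
#' @param method Scoring method; only `"mean_z"`.
#' @return data.frame with columns `pixel`, `score`; attribute
#'   `"features_used"` lists the features that entered the score.
#' @export
signature_score <- function(nm, genes, method = c("mean_z")) {
  method <- match.arg(method)
  stopifnot(inherits(nm, "normalized_matrix"))
  genes <- unique(genes)
  present <- intersect(genes, rownames(nm$values))
  absent <- setdiff(genes, present)
  if (length(absent))
    .warnf("signature feature(s) not in matrix, skipped: %s",
           paste(absent, collapse = ", "))
  if (!length(present))
    .stopf("none of the signature features are present in the matrix")
  sub <- nm$values[present, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  keep <- sds > 0
  if (!any(keep))
    .stopf("all signature features are constant across pixels")
  sub <- sub[keep, , drop = FALSE]
  z <- sweep(sweep(sub, 1L, rowMeans(sub)), 1L, sds[keep], "/")
  structure(data.frame(pixel = colnames(nm$values),
                       score = colMeans(z),
                       stringsAsFactors = FALSE, row.names = NULL),
            features_used = rownames(sub),
            class = c("signature_score", "data.frame"))
}

#' Feature ids for the Tph (peripheral helper T cell) signature
#'
#' The signature is defined by LAG3, PD-1 and CXCR6.  PD-1 is the protein
#' name; its gene symbol is PDCD1, and on ADT panels the corresponding
#' antibody is anti-CD279.  The mapping is a convention shipped here for
#' convenience — any feature list can be passed to [signature_score()].
#'
#' @param modality `"RNA"` (gene symbols) or `"protein"` (ADT names).
#' @return Character vector of feature ids.
#' @export
tph_signature <- function(modality = c("RNA", "protein")) {
  modality <- match.arg(modality)
  if (modality == "RNA") c("LAG3", "PDCD1", "CXCR6")
  else c("CD223", "CD279", "CXCR6")
}

#' Pseudo-bulk aggregation of a spatial matrix
#'
#' Sums counts over pixels per feature, after excluding pixels whose total
#' UMI count is below `min_total_umi` (default 10, mirroring the minimum-UMI
#' cell filter used when comparing against single-cell profiles).  Returns
#' both raw totals and their CLR transform for correlation against external
#' bulk or single-cell profiles.
#'
#' @param m A `spatial_counts` object.
#' @param min_total_umi Minimum per-pixel total UMI to include a pixel.
#' @return List with `totals` (named numeric), `clr` (named numeric),
#'   `n_pixels_used`.
#' @export
pseudobulk <- function(m, min_total_umi = 10L) {
  stopifnot(inherits(m, "spatial_counts"))
  cs <- Matrix::colSums(m$counts)
  use <- cs >= min_total_umi
  tot <- Matrix::rowSums(m$counts[, use, drop = FALSE])
  lt <- log1p(tot)
  list(totals = stats::setNames(as.numeric(tot), rownames(m$counts)),
       clr = stats::setNames(as.numeric(lt - mean(lt)), rownames(m$counts)),
       n_pixels_used = sum(use))
}

#' Write per-pixel QC as TSV plus a JSON summary
#'
#' @param qc A `pixel_qc` object.
#' @param tsv_path,json_path Output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_qc <- function(qc, tsv_path, json_path = NULL) {
  stopifnot(inherits(qc, "pixel_qc"))
  utils::write.table(qc$per_pixel, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(qc$summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}
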