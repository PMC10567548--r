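# Synthetic data: ground-truth tissue models and FASTQ read simulation.
#
# The simulator emulates the read architecture of a two-level deterministic
# in-tissue barcoding run: Read 1 carries the payload (ADT tag or transcript
# insert), Read 2 carries UMI + column barcode B + ligation linker + row
# barcode A.  Every emitted read is logged in a provenance table, which is the
# oracle for all recovery tests.

#' Sequencing/PCR error model for the simulator
#'
#' @param substitution_rate Per-base substitution probability in `[0, 0.25)`.
#' @param pcr_duplication Mean read pairs per molecule (>= 1); duplicate
#'   counts are drawn as 1 + geometric so the mean equals this value.
#' @param seed Integer RNG seed; the whole simulation is deterministic given
#'   the seed.
#' @return An `error_model` list.
#' @export
error_model <- function(substitution_rate = 0, pcr_duplication = 1, seed = 1L) {
  if (substitution_rate < 0 || substitution_rate >= 0.25)
    .stopf("substitution_rate must be in [0, 0.25)")
  if (pcr_duplication < 1) .stopf("pcr_duplication must be >= 1")
  structure(list(substitution_rate = substitution_rate,
                 pcr_duplication = pcr_duplication,
                 seed = as.integer(seed)),
            class = "error_model")
}

#' Construct a ground-truth tissue model
#'
#' A tissue model is a pixel grid partitioned into spatial domains, each with
#' its own mean-molecule profile per gene and per antibody.  Molecule counts
#' are later drawn Poisson around these means; `background_rate` adds a
#' nonspecific-binding mean to every antibody in every pixel.
#'
#' @param n_rows,n_cols Grid size (rows indexed by barcode A, columns by
#'   barcode B); at most 50 x 50.
#' @param domains List of domains, each a list with `domain_id` (string),
#'   `mask` (logical `n_rows x n_cols` matrix), `rna_profile` and
#'   `protein_profile` (named non-negative numeric vectors of mean molecules
#'   per pixel).  Masks must partition the grid: every pixel in exactly one
#'   domain.
#' @param background_rate Mean nonspecific ADT molecules per pixel per
#'   antibody.
#' @return A `tissue_model`.
#' @export
tissue_model <- function(n_rows, n_cols, domains, background_rate = 0) {
  if (n_rows < 1L || n_cols < 1L || n_rows > 50L || n_cols > 50L)
    .stopf("grid must be between 1x1 and 50x50")
  if (!length(domains)) .stopf("tissue model needs at least one domain")
  cover <- matrix(0L, n_rows, n_cols)
  for (d in domains) {
    if (!all(c("domain_id", "mask", "rna_profile", "protein_profile") %in% names(d)))
      .stopf("each domain needs domain_id, mask, rna_profile, protein_profile")
    if (!all(dim(d$mask) == c(n_rows, n_cols)))
      .stopf("domain '%s': mask dimensions do not match the grid", d$domain_id)
    if (any(d$rna_profile < 0) || any(d$protein_profile < 0))
      .stopf("domain '%s': profiles must be non-negative", d$domain_id)
    cover <- cover + d$mask
  }
  if (any(cover != 1L))
    .stopf("domain masks must cover every pixel exactly once (%d pixels violate this)",
           sum(cover != 1L))
  assignment <- matrix(NA_integer_, n_rows, n_cols)
  for (i in seq_along(domains)) assignment[domains[[i]]$mask] <- i
  gene_ids <- sort(unique(unlist(lapply(domains, function(d) names(d$rna_profile)))))
  ab_ids <- unique(unlist(lapply(domains, function(d) names(d$protein_profile))))
  rna_means <- sapply(domains, function(d) {
    v <- stats::setNames(numeric(length(gene_ids)), gene_ids)
    v[names(d$rna_profile)] <- d$rna_profile
    v
  })
  protein_means <- sapply(domains, function(d) {
    v <- stats::setNames(numeric(length(ab_ids)), ab_ids)
    v[names(d$protein_profile)] <- d$protein_profile
    v
  })
  rna_means <- matrix(rna_means, nrow = length(gene_ids),
                      dimnames = list(gene_ids, NULL))
  protein_means <- matrix(protein_means, nrow = length(ab_ids),
                          dimnames = list(ab_ids, NULL))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 domain_ids = vapply(domains, `[[`, "", "domain_id"),
                 assignment = assignment,
                 rna_means = rna_means, protein_means = protein_means,
                 background_rate = background_rate),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("Tissue model: %dx%d pixels, %d domains (%s)\n",
              x$n_rows, x$n_cols, length(x$domain_ids),
              paste(x$domain_ids, collapse = ", ")))
  cat(sprintf("  %d genes, %d antibodies, ADT background rate %.3g\n",
              nrow(x$rna_means), nrow(x$protein_means), x$background_rate))
  invisible(x)
}

# circular blob mask
.blob_mask <- function(n_rows, n_cols, centre, radius) {
  outer(seq_len(n_rows), seq_len(n_cols),
        function(r, c) (r - centre[1L])^2 + (c - centre[2L])^2 <= radius^2)
}

#' Build a demo tissue model from a named preset
#'
#' Presets sketch the domain geometries seen in lymphoid and skin tissue:
#' `spleen_like` has red/white pulp plus a capsule rim, `tonsil_like` has
#' extrafollicular tissue, a crypt stripe and germinal-centre dark/light
#' zones, and `skin_like` has epidermis/dermis/vascular stripes plus a
#' localized immune-infiltrate blob.  Each domain receives a disjoint set of
#' marker genes and marker antibodies whose mean is `enrichment`-fold the base
#' level; blob positions are randomized by the seed, the domain count is fixed
#' per preset.
#'
#' @param preset One of `"spleen_like"`, `"tonsil_like"`, `"skin_like"`.
#' @param seed Integer RNG seed.
#' @param n_rows,n_cols Grid size.
#' @param gene_ids,antibody_ids Feature universes to draw marker sets from.
#' @param base_rna,base_protein Baseline mean molecules per pixel.
#' @param enrichment Fold-change of a domain's markers inside the domain.
#' @param background_rate Nonspecific ADT mean per pixel per antibody.
#' @return A `tissue_model`.
#' @export
make_demo_tissue <- function(preset = c("spleen_like", "tonsil_like", "skin_like"),
                             seed = 1L, n_rows = 10L, n_cols = 10L,
                             gene_ids = sprintf("GENE%03d", 1:20),
                             antibody_ids = c(sprintf("AB%03d", 1:21),
                                              sprintf("IsoCtrl%02d", 1:9)),
                             base_rna = 0.5, base_protein = 2,
                             enrichment = 10, background_rate = 0.1) {
  preset <- match.arg(preset)
  .with_seed(seed, {
    R <- n_rows; C <- n_cols
    all_false <- matrix(FALSE, R, C)
    masks <- switch(preset,
      spleen_like = {
        capsule <- matrix(FALSE, R, C)
        capsule[1L, ] <- TRUE; capsule[R, ] <- TRUE
        white <- all_false
        for (k in 1:2) {
          ctr <- c(sample(3:(R - 2L), 1L), sample(3:(C - 2L), 1L))
          white <- white | .blob_mask(R, C, ctr, max(2, min(R, C) / 5))
        }
        white <- white & !capsule
        list(red_pulp = !white & !capsule, white_pulp = white, capsule = capsule)
      },
      tonsil_like = {
        crypt <- all_false
        crypt[, sample(seq_len(max(1L, C %/% 4L)), 1L)] <- TRUE
        ctr <- c(sample(3:(R - 2L), 1L), sample((C %/% 2L):(C - 2L), 1L))
        dark <- .blob_mask(R, C, ctr, max(1.5, min(R, C) / 6)) & !crypt
        light <- .blob_mask(R, C, ctr, max(2.5, min(R, C) / 4)) & !dark & !crypt
        list(extrafollicular = !crypt & !dark & !light,
             crypt = crypt, gc_light = light, gc_dark = dark)
      },
      skin_like = {
        epi <- all_false; epi[seq_len(max(1L, R %/% 5L)), ] <- TRUE
        vasc <- all_false; vasc[(R - max(1L, R %/% 5L) + 1L):R, ] <- TRUE
        ctr <- c(sample((R %/% 3L):(2L * R %/% 3L), 1L), sample(2:(C - 1L), 1L))
        blob <- .blob_mask(R, C, ctr, max(1.5, min(R, C) / 5)) & !epi & !vasc
        list(dermis = !epi & !vasc & !blob, epidermis = epi,
             vascular = vasc, injection_site = blob)
      })
    # some blobs can end up empty on tiny grids; drop empty masks except the first
    keep <- vapply(masks, any, TRUE); keep[1L] <- TRUE
    masks <- masks[keep]
    ndom <- length(masks)
    gene_sets <- split(gene_ids, rep(seq_len(ndom), length.out = length(gene_ids)))
    ab_sets <- split(antibody_ids, rep(seq_len(ndom), length.out = length(antibody_ids)))
    domains <- lapply(seq_len(ndom), function(i) {
      rna <- stats::setNames(rep(base_rna, length(gene_ids)), gene_ids)
      rna[gene_sets[[i]]] <- base_rna * enrichment
      prot <- stats::setNames(rep(base_protein, length(antibody_ids)), antibody_ids)
      prot[ab_sets[[i]]] <- base_protein * enrichment
      list(domain_id = names(masks)[i], mask = masks[[i]],
           rna_profile = rna, protein_profile = prot)
    })
    tissue_model(R, C, domains, background_rate = background_rate)
  })
}

#' Generate a toy transcriptome
#'
#' Random transcripts of fixed length, one per gene; deterministic for a given
#' seed.  Intended for the exact-match toy assigner, not for alignment.
#'
#' @param n_genes Number of genes (`GENE001`, `GENE002`, ...).
#' @param tx_length Transcript length in nt.
#' @param seed Integer RNG seed.
#' @return Named character vector of transcript sequences.
#' @export
generate_fixture_transcriptome <- function(n_genes = 20L, tx_length = 300L,
                                           seed = 1L) {
  .with_seed(seed,
    stats::setNames(.rand_dna(n_genes, tx_length),
                    sprintf("GENE%03d", seq_len(n_genes))))
}

#' Write a transcriptome as FASTA
#' @param tx Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcriptome <- function(tx, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tx), path, width = 60L)
  invisible(path)
}

# Accept a FASTA path, DNAStringSet or named character vector.
.as_transcriptome <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (methods::is(x, "DNAStringSet"))
    x <- stats::setNames(as.character(x), sub("[ \t].*$", "", names(x)))
  if (!is.character(x) || is.null(names(x)))
    .stopf("transcriptome must be a FASTA path or a named sequence vector")
  x
}

# Draw per-pixel Poisson molecule tables for one modality.
# means: features x domains matrix.  Returns data.frame(row, col, feature).
.draw_molecules <- function(model, means) {
  out <- vector("list", length(model$domain_ids))
  for (d in seq_along(model$domain_ids)) {
    px <- which(model$assignment == d, arr.ind = TRUE)
    if (!nrow(px)) next
    nf <- nrow(means)
    mu <- rep(means[, d], times = nrow(px))
    counts <- stats::rpois(length(mu), mu)
    if (!sum(counts)) next
    keep <- counts > 0L
    out[[d]] <- data.frame(
      row = rep(rep(px[, 1L], each = nf)[keep], counts[keep]),
      col = rep(rep(px[, 2L], each = nf)[keep], counts[keep]),
      feature = rep(rep(rownames(means), times = nrow(px))[keep], counts[keep]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(row = integer(0), col = integer(0),
                      feature = character(0), stringsAsFactors = FALSE)
  out
}

# Assemble Read 2 from per-read segment values according to the layout.
.assemble_read2 <- function(layout, umi, bcB, bcA) {
  segs <- list(umi = umi, bcB = bcB,
               linker = rep(layout$linker_seq, length(umi)), bcA = bcA)
  offs <- vapply(c("umi", "bcB", "linker", "bcA"),
                 function(nm) layout[[nm]][1L], 0L)
  ord <- names(sort(offs))
  # segments must be contiguous from 0 for assembly
  pos <- 0L
  for (nm in ord) {
    if (layout[[nm]][1L] != pos)
      .stopf("simulator requires a contiguous layout starting at offset 0")
    pos <- pos + layout[[nm]][2L]
  }
  r2 <- do.call(paste0, segs[ord])
  if (layout$read2_length > layout$span)
    r2 <- paste0(r2, strrep("A", layout$read2_length - layout$span))
  r2
}

#' Simulate a spatial co-profiling sequencing run
#'
#' Draws molecule counts Poisson around the tissue model's per-domain means
#' (plus the ADT background rate for the protein library), assigns each
#' molecule a uniform-random UMI, duplicates it into `>= 1` read pairs, and
#' writes two paired-end gzipped FASTQ libraries (RNA and ADT) whose Read 2
#' encodes the pixel's spatial address.  Substitution errors are applied
#' uniformly to both reads.  Output is byte-identical for identical seeds.
#'
#' @param model A [tissue_model()].
#' @param panel An [adt_panel()] covering all antibody ids in the model.
#' @param transcriptome FASTA path or named sequence vector covering all gene
#'   ids in the model.
#' @param whitelists List with elements `A` and `B` ([barcode_whitelist()]s);
#'   the grid must fit inside them.
#' @param layout A [read_layout()]; must be contiguous from offset 0.
#' @param err An [error_model()].
#' @param out_dir Output directory for the FASTQ files, ground-truth matrices
#'   and provenance log.
#' @param rna_insert_length Length of the transcript substring placed in
#'   Read 1 of the RNA library.
#' @return A `sim_run` list: FASTQ paths (`rna_r1`, `rna_r2`, `adt_r1`,
#'   `adt_r2`), `provenance` (read_id, modality, row, col, feature, umi),
#'   ground-truth `spatial_counts` matrices (`truth$rna_molecules`,
#'   `truth$rna_umi`, `truth$adt_molecules`, `truth$adt_umi`), and the inputs.
#' @export
simulate_run <- function(model, panel, transcriptome, whitelists,
                         layout = read_layout(), err = error_model(),
                         out_dir = tempfile("simrun"),
                         rna_insert_length = 90L) {
  stopifnot(inherits(model, "tissue_model"), inherits(panel, "adt_panel"),
            inherits(err, "error_model"))
  tx <- .as_transcriptome(transcriptome)
  missing_genes <- setdiff(rownames(model$rna_means), names(tx))
  if (length(missing_genes))
    .stopf("gene id(s) not in transcriptome: %s",
           paste(utils::head(missing_genes, 5L), collapse = ", "))
  missing_abs <- setdiff(rownames(model$protein_means), panel$antibody_id)
  if (length(missing_abs))
    .stopf("antibody id(s) not in panel: %s",
           paste(utils::head(missing_abs, 5L), collapse = ", "))
  wlA <- whitelists$A; wlB <- whitelists$B
  stopifnot(inherits(wlA, "barcode_whitelist"), inherits(wlB, "barcode_whitelist"))
  if (model$n_rows > nrow(wlA) || model$n_cols > nrow(wlB))
    .stopf("grid (%dx%d) exceeds whitelist sizes (%dx%d)",
           model$n_rows, model$n_cols, nrow(wlA), nrow(wlB))
  if (attr(wlA, "bc_length") != layout$bcA[2L] ||
      attr(wlB, "bc_length") != layout$bcB[2L])
    .stopf("whitelist barcode lengths do not match the layout")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  umi_len <- layout$umi[2L]

  .with_seed(err$seed, {
    sim_one <- function(modality) {
      means <- if (modality == "RNA") model$rna_means
               else model$protein_means + model$background_rate
      mol <- .draw_molecules(model, means)
      n_mol <- nrow(mol)
      mol$umi <- .rand_dna(n_mol, umi_len)
      dup <- if (err$pcr_duplication == 1 || n_mol == 0L) rep(1L, n_mol)
             else 1L + stats::rgeom(n_mol, 1 / err$pcr_duplication)
      ridx <- rep.int(seq_len(n_mol), dup)
      reads <- mol[ridx, , drop = FALSE]
      n_reads <- nrow(reads)
      reads$read_id <- sprintf("%s_%07d", modality, seq_len(n_reads))
      r2 <- .assemble_read2(layout, reads$umi,
                            wlB$seq[reads$col], wlA$seq[reads$row])
      if (modality == "RNA") {
        txs <- tx[reads$feature]
        txlen <- nchar(txs)
        span <- pmax(txlen - rna_insert_length + 1L, 1L)
        start <- 1L + floor(stats::runif(n_reads) * span)
        r1 <- substr(txs, start, start + rna_insert_length - 1L)
        short <- nchar(r1) < rna_insert_length
        if (any(short))
          r1[short] <- paste0(r1[short],
                              strrep("A", rna_insert_length - nchar(r1[short])))
        r1 <- unname(r1)
      } else {
        tags <- panel$tag_seq[match(reads$feature, panel$antibody_id)]
        prefix <- strrep("T", layout$r1_tag[1L])
        r1 <- paste0(prefix, tags, strrep("A", 10L))
      }
      r1 <- .mutate_seqs(r1, err$substitution_rate)
      r2 <- .mutate_seqs(r2, err$substitution_rate)
      list(mol = mol, reads = reads, r1 = r1, r2 = r2)
    }
    rna <- sim_one("RNA")
    adt <- sim_one("ADT")

    paths <- list(rna_r1 = file.path(out_dir, "rna_R1.fastq.gz"),
                  rna_r2 = file.path(out_dir, "rna_R2.fastq.gz"),
                  adt_r1 = file.path(out_dir, "adt_R1.fastq.gz"),
                  adt_r2 = file.path(out_dir, "adt_R2.fastq.gz"))
    .write_fastq_gz(rna$reads$read_id, rna$r1, paths$rna_r1)
    .write_fastq_gz(rna$reads$read_id, rna$r2, paths$rna_r2)
    .write_fastq_gz(adt$reads$read_id, adt$r1, paths$adt_r1)
    .write_fastq_gz(adt$reads$read_id, adt$r2, paths$adt_r2)

    prov <- rbind(
      data.frame(read_id = rna$reads$read_id, modality = "RNA",
                 row = rna$reads$row, col = rna$reads$col,
                 feature = rna$reads$feature, umi = rna$reads$umi,
                 stringsAsFactors = FALSE),
      data.frame(read_id = adt$reads$read_id, modality = "protein",
                 row = adt$reads$row, col = adt$reads$col,
                 feature = adt$reads$feature, umi = adt$reads$umi,
                 stringsAsFactors = FALSE))
    utils::write.table(prov, file.path(out_dir, "provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    gt_matrix <- function(mol, modality, kind) {
      if (kind == "umi")
        mol <- unique(mol[, c("row", "col", "feature", "umi")])
      agg <- stats::aggregate(list(count = rep(1L, nrow(mol))),
                              mol[, c("row", "col", "feature")], sum)
      features <- if (modality == "protein") panel$antibody_id
                  else sort(unique(agg$feature))
      build_matrix(agg, modality = modality, features = features,
                   grid = c(model$n_rows, model$n_cols))
    }
    truth <- list(rna_molecules = gt_matrix(rna$mol, "RNA", "mol"),
                  rna_umi = gt_matrix(rna$mol, "RNA", "umi"),
                  adt_molecules = gt_matrix(adt$mol, "protein", "mol"),
                  adt_umi = gt_matrix(adt$mol, "protein", "umi"))
    write_counts_dir(truth$rna_umi, file.path(out_dir, "truth_rna"))
    write_counts_dir(truth$adt_umi, file.path(out_dir, "truth_protein"))

    structure(c(paths,
                list(provenance = prov, truth = truth, model = model,
                     panel = panel, layout = layout, whitelists = whitelists,
                     err = err, out_dir = out_dir,
                     n_read_pairs = c(RNA = nrow(rna$reads),
                                      protein = nrow(adt$reads)),
                     n_molecules = c(RNA = nrow(rna$mol),
                                     protein = nrow(adt$mol)))),
              class = "sim_run")
  })
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("Simulated run in %s\n", x$out_dir))
  cat(sprintf("  RNA: %d molecules -> %d read pairs\n",
              x$n_molecules[["RNA"]], x$n_read_pairs[["RNA"]]))
  cat(sprintf("  ADT: %d molecules -> %d read pairs\n",
              x$n_molecules[["protein"]], x$n_read_pairs[["protein"]]))
  invisible(x)
}
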