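# End-to-end orchestration: run configuration, the full pipeline, fixture
# generation, and tissue-model YAML round-trips.

.default_config <- function() {
  list(
    seed = 1L,
    layout = list(umi = c(0L, 10L), bcB = c(10L, 8L), linker = c(18L, 30L),
                  bcA = c(48L, 8L), linker_seq = DEFAULT_LINKER,
                  r1_tag = c(0L, 15L), read2_length = NULL),
    paths = list(whitelist_a = NULL, whitelist_b = NULL, panel = NULL,
                 transcriptome = NULL),
    demux = list(max_hamming_bc = 1L, max_hamming_linker = 2L),
    quantify = list(collapse_mode = "exact", kmer_k = 31L,
                    adt_max_hamming = 1L, drop_unobserved_genes = TRUE),
    normalize = list(clr_margin = "per_pixel", lognorm_scale = 1e4),
    pseudobulk = list(min_total_umi = 10L))
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, rejects unknown keys, and materializes every default
#' into the returned list so the echoed configuration is complete.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) .stopf("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    for (sec in names(user)) {
      if (is.list(cfg[[sec]]) && is.list(user[[sec]])) {
        bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
        if (length(bad))
          .stopf("unknown config key(s) in '%s': %s", sec,
                 paste(bad, collapse = ", "))
        cfg[[sec]][names(user[[sec]])] <- user[[sec]]
      } else {
        cfg[[sec]] <- user[[sec]]
      }
    }
  }
  structure(cfg, class = "run_config")
}

# layout object from the config section
.config_layout <- function(cfg) {
  l <- cfg$layout
  read_layout(umi = unlist(l$umi), bcB = unlist(l$bcB),
              linker = unlist(l$linker), bcA = unlist(l$bcA),
              linker_seq = l$linker_seq, r1_tag = unlist(l$r1_tag),
              read2_length = l$read2_length)
}

# md5 of the canonical JSON form of the config
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on a pair of libraries
#'
#' Demultiplexes the RNA and ADT libraries, assigns payloads to features (toy
#' k-mer assigner for RNA unless an external assignment table is given; tag
#' matching for ADTs), collapses UMIs, builds both spatial count matrices,
#' computes per-pixel QC, CLR-normalizes the protein matrix and
#' log-normalizes the RNA matrix, and writes everything plus a manifest to
#' `out_dir`.  Deterministic given inputs and configuration; matrix files are
#' written via write-then-rename so a failed run leaves no truncated matrix.
#'
#' @param config A `run_config` from [load_config()]; `config$paths` must
#'   name the whitelists, panel and transcriptome.
#' @param rna_r1,rna_r2,adt_r1,adt_r2 FASTQ paths for the two libraries.
#' @param out_dir Output directory.
#' @param rna_assignments Optional TSV path of external read-to-gene
#'   assignments (see [load_external_assignments()]); replaces the toy
#'   assigner.
#' @return List with the two `spatial_counts` matrices (`rna`, `protein`),
#'   QC objects, demux stats, and `out_dir`.
#' @export
run_pipeline <- function(config, rna_r1, rna_r2, adt_r1, adt_r2, out_dir,
                         rna_assignments = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  for (p in c(config$paths$whitelist_a, config$paths$whitelist_b,
              config$paths$panel, config$paths$transcriptome)) {
    if (is.null(p) || !file.exists(p))
      .stopf("config error: required input missing or not found: %s",
             if (is.null(p)) "(unset path)" else p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- stage("config", .config_layout(config))
  wlA <- stage("load", load_whitelist(config$paths$whitelist_a, "A",
                                      config$demux$max_hamming_bc))
  wlB <- stage("load", load_whitelist(config$paths$whitelist_b, "B",
                                      config$demux$max_hamming_bc))
  panel <- stage("load", load_panel(config$paths$panel))
  grid <- c(nrow(wlA), nrow(wlB))

  dm_rna <- stage("demux_rna",
    demux_library(rna_r1, rna_r2, layout, wlA, wlB,
                  config$demux$max_hamming_bc, config$demux$max_hamming_linker,
                  modality = "RNA"))
  dm_adt <- stage("demux_adt",
    demux_library(adt_r1, adt_r2, layout, wlA, wlB,
                  config$demux$max_hamming_bc, config$demux$max_hamming_linker,
                  modality = "protein"))

  rna_rec <- dm_rna$records
  if (is.null(rna_assignments)) {
    idx <- stage("assign_rna",
                 build_kmer_index(config$paths$transcriptome,
                                  config$quantify$kmer_k))
    rna_rec$feature <- stage("assign_rna",
                             assign_transcript_toy(rna_rec$payload, idx))
  } else {
    ext <- stage("assign_rna", load_external_assignments(rna_assignments))
    rna_rec$feature <- ext$gene[match(rna_rec$read_id, ext$read_id)]
  }
  rna_rec <- rna_rec[!is.na(rna_rec$feature), , drop = FALSE]

  adt_rec <- dm_adt$records
  adt_rec$feature <- stage("assign_adt",
    match_adt_tag(adt_rec$payload, panel,
                  max_hamming = config$quantify$adt_max_hamming,
                  r1_tag = layout$r1_tag))
  adt_rec <- adt_rec[!is.na(adt_rec$feature), , drop = FALSE]

  mode <- config$quantify$collapse_mode
  rna_counts <- stage("collapse", collapse_umis(rna_rec, mode))
  adt_counts <- stage("collapse", collapse_umis(adt_rec, mode))

  rna_m <- stage("matrix",
    build_matrix(rna_counts, "RNA", features = NULL, grid = grid,
                 drop_unobserved = config$quantify$drop_unobserved_genes))
  adt_m <- stage("matrix",
    build_matrix(adt_counts, "protein", features = panel$antibody_id,
                 grid = grid))

  qc_rna <- qc_metrics(rna_m)
  qc_adt <- qc_metrics(adt_m)
  norm_adt <- stage("normalize", clr_normalize(adt_m, config$normalize$clr_margin))
  norm_rna <- if (ncol(rna_m$counts) && nrow(rna_m$counts))
    stage("normalize", lognorm_rna(rna_m, config$normalize$lognorm_scale))
  else NULL

  # outputs
  write_counts_dir(rna_m, file.path(out_dir, "rna"))
  write_counts_dir(adt_m, file.path(out_dir, "protein"))
  write_qc(qc_rna, file.path(out_dir, "qc_rna.tsv"),
           file.path(out_dir, "qc_rna_summary.json"))
  write_qc(qc_adt, file.path(out_dir, "qc_protein.tsv"),
           file.path(out_dir, "qc_protein_summary.json"))
  .write_normalized <- function(nm, dir_) {
    if (is.null(nm)) return(invisible(NULL))
    dir.create(dir_, showWarnings = FALSE, recursive = TRUE)
    tmp <- file.path(dir_, ".matrix.mtx.tmp")
    Matrix::writeMM(methods::as(Matrix::Matrix(nm$values, sparse = TRUE),
                                "generalMatrix"), tmp)
    file.rename(tmp, file.path(dir_, "matrix.mtx"))
    writeLines(rownames(nm$values), file.path(dir_, "features.tsv"))
    writeLines(colnames(nm$values), file.path(dir_, "pixels.tsv"))
    jsonlite::write_json(list(method = nm$method, modality = nm$modality),
                         file.path(dir_, "method.json"), auto_unbox = TRUE)
  }
  .write_normalized(norm_adt, file.path(out_dir, "protein_clr"))
  .write_normalized(norm_rna, file.path(out_dir, "rna_lognorm"))

  stats <- list(demux_rna = unclass(dm_rna$stats),
                demux_adt = unclass(dm_adt$stats),
                rna_assigned = nrow(rna_rec), adt_assigned = nrow(adt_rec))
  manifest <- list(package = "spatialcite",
                   version = as.character(utils::packageVersion("spatialcite")),
                   config = unclass(config),
                   config_hash = .config_hash(config),
                   stats = stats)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  list(rna = rna_m, protein = adt_m, qc = list(RNA = qc_rna, protein = qc_adt),
       norm = list(protein_clr = norm_adt, rna_lognorm = norm_rna),
       stats = stats, out_dir = out_dir)
}

#' Serialize a tissue model to YAML
#'
#' @param model A [tissue_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tissue_model <- function(model, path) {
  stopifnot(inherits(model, "tissue_model"))
  doms <- lapply(seq_along(model$domain_ids), function(i) {
    px <- which(model$assignment == i, arr.ind = TRUE)
    list(domain_id = model$domain_ids[i],
         rows = as.integer(px[, 1L]), cols = as.integer(px[, 2L]),
         rna_profile = as.list(model$rna_means[, i]),
         protein_profile = as.list(model$protein_means[, i]))
  })
  yaml::write_yaml(list(n_rows = model$n_rows, n_cols = model$n_cols,
                        background_rate = model$background_rate,
                        domains = doms), path)
  invisible(path)
}

#' Read a tissue model from YAML
#'
#' @param path Path written by [write_tissue_model()].
#' @return A [tissue_model()].
#' @export
read_tissue_model <- function(path) {
  y <- yaml::read_yaml(path)
  doms <- lapply(y$domains, function(d) {
    mask <- matrix(FALSE, y$n_rows, y$n_cols)
    mask[cbind(as.integer(d$rows), as.integer(d$cols))] <- TRUE
    list(domain_id = d$domain_id, mask = mask,
         rna_profile = unlist(d$rna_profile),
         protein_profile = unlist(d$protein_profile))
  })
  tissue_model(y$n_rows, y$n_cols, doms, background_rate = y$background_rate)
}

#' Write a self-consistent fixture set
#'
#' Generates and writes everything a run needs: whitelists for both axes, an
#' ADT panel, a toy transcriptome, and a demo tissue model.  The `small`
#' scale (10x10 grid, 20 genes, 30 ADTs) is sized for fast tests; the `full`
#' scale uses 50-barcode whitelists and panels sized like the commercial
#' cocktails (273-plex human and 189-plex mouse, nine isotype controls each).
#'
#' @param outdir Output directory.
#' @param seed Integer RNG seed; identical seeds give identical fixtures.
#' @param scale `"small"` or `"full"`.
#' @return Named list of file paths (`whitelist_a`, `whitelist_b`, `panel`,
#'   `panel_mouse` [full scale only], `transcriptome`, `tissue`).
#' @export
make_fixtures <- function(outdir, seed = 1L, scale = c("small", "full")) {
  scale <- match.arg(scale)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n_bc <- if (scale == "small") 10L else 50L
  n_adt <- if (scale == "small") 30L else 273L
  n_genes <- if (scale == "small") 20L else 40L
  wl <- generate_fixture_whitelists(n_bc, length = 8L, min_dist = 3L,
                                    seed = seed)
  panel <- generate_fixture_panel(n_adt, n_isotype = 9L, species = "human",
                                  seed = seed + 1L)
  tx <- generate_fixture_transcriptome(n_genes, seed = seed + 2L)
  grid <- if (scale == "small") c(10L, 10L) else c(50L, 50L)
  model <- make_demo_tissue("spleen_like", seed = seed + 3L,
                            n_rows = grid[1L], n_cols = grid[2L],
                            gene_ids = names(tx),
                            antibody_ids = panel$antibody_id)
  paths <- list(whitelist_a = file.path(outdir, "whitelist_a.tsv"),
                whitelist_b = file.path(outdir, "whitelist_b.tsv"),
                panel = file.path(outdir, "panel.tsv"),
                transcriptome = file.path(outdir, "transcriptome.fasta"),
                tissue = file.path(outdir, "tissue.yaml"))
  write_whitelist(wl$A, paths$whitelist_a)
  write_whitelist(wl$B, paths$whitelist_b)
  write_panel(panel, paths$panel)
  write_transcriptome(tx, paths$transcriptome)
  write_tissue_model(model, paths$tissue)
  if (scale == "full") {
    mouse <- generate_fixture_panel(189L, n_isotype = 9L, species = "mouse",
                                    seed = seed + 4L)
    paths$panel_mouse <- file.path(outdir, "panel_mouse.tsv")
    write_panel(mouse, paths$panel_mouse)
  }
  paths
}
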