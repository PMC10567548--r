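# ADT panels: antibody -> DNA tag tables, including isotype controls.

#' Construct an ADT panel
#'
#' An antibody-derived-tag (ADT) panel maps each antibody to the DNA tag
#' sequence conjugated to it.  Commercial cocktails of this kind run to a few
#' hundred antibodies (e.g. 189-plex mouse, 273-plex human) and include a
#' handful of isotype-control antibodies that report nonspecific binding.
#'
#' @param df data.frame with columns `antibody_id` (unique short strings),
#'   `tag_seq` (equal-length A/C/G/T strings, unique within the panel) and
#'   `is_isotype_control` (logical).  An optional `target_species` column
#'   (`"human"`/`"mouse"`) is carried through.
#' @return An `adt_panel` data.frame with attributes `tag_length` and
#'   `n_isotype`.
#' @export
adt_panel <- function(df) {
  need <- c("antibody_id", "tag_seq", "is_isotype_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("panel is missing column(s): %s",
                           paste(miss, collapse = ", "))
  if (nrow(df) < 1L) .stopf("panel has no entries")
  df$antibody_id <- as.character(df$antibody_id)
  df$tag_seq <- toupper(as.character(df$tag_seq))
  df$is_isotype_control <- as.logical(df$is_isotype_control)
  if (anyNA(df$is_isotype_control))
    .stopf("panel: is_isotype_control must be TRUE/FALSE (or 0/1)")
  bad <- which(!.is_dna(df$tag_seq))
  if (length(bad)) .stopf("panel row %d: tag_seq '%s' is not A/C/G/T",
                          bad[1L], df$tag_seq[bad[1L]])
  if (length(unique(nchar(df$tag_seq))) != 1L)
    .stopf("panel: tag sequences have mixed lengths")
  dup <- which(duplicated(df$tag_seq))
  if (length(dup)) .stopf("panel row %d: duplicate tag_seq '%s'",
                          dup[1L], df$tag_seq[dup[1L]])
  if (anyDuplicated(df$antibody_id))
    .stopf("panel: duplicate antibody_id '%s'",
           df$antibody_id[duplicated(df$antibody_id)][1L])
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            tag_length = nchar(df$tag_seq[1L]),
            n_isotype = sum(df$is_isotype_control),
            class = c("adt_panel", "data.frame"))
}

#' Load an ADT panel from a TSV file
#'
#' Expects a header row with columns `antibody_id`, `tag_seq`,
#' `is_isotype_control` (and optionally `target_species`); `#` comment lines
#' are allowed.
#'
#' @param path Path to a tab-separated panel table.
#' @return An `adt_panel`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) .stopf("panel file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) .stopf("panel file is empty: %s", path)
  adt_panel(df)
}

#' Write an ADT panel as TSV
#'
#' @param panel An `adt_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "adt_panel"))
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.adt_panel <- function(x, ...) {
  cat(sprintf("ADT panel: %d antibodies (%d isotype controls), %d-nt tags\n",
              nrow(x), attr(x, "n_isotype"), attr(x, "tag_length")))
  invisible(x)
}

#' Generate a synthetic ADT panel
#'
#' Random unique tags of fixed length with the last `n_isotype` entries
#' flagged as isotype controls, emulating the structure of commercial ADT
#' cocktails.  Deterministic for a given seed.
#'
#' @param n Number of antibodies.
#' @param tag_length Tag length in nt.
#' @param n_isotype Number of isotype-control entries.
#' @param species `"human"` or `"mouse"` (annotation only).
#' @param seed Integer RNG seed.
#' @return An `adt_panel`.
#' @export
generate_fixture_panel <- function(n, tag_length = 15L, n_isotype = min(9L, n - 1L),
                                   species = c("human", "mouse"), seed = 1L) {
  species <- match.arg(species)
  if (n_isotype >= n) .stopf("n_isotype must be smaller than n")
  .with_seed(seed, {
    tags <- unique(.rand_dna(4L * n, tag_length))
    if (length(tags) < n)
      .stopf("could not draw %d unique %d-nt tags", n, tag_length)
    tags <- tags[seq_len(n)]
    iso <- c(rep(FALSE, n - n_isotype), rep(TRUE, n_isotype))
    ids <- character(n)
    ids[!iso] <- sprintf("AB%03d", seq_len(sum(!iso)))
    ids[iso] <- sprintf("IsoCtrl%02d", seq_len(sum(iso)))
    adt_panel(data.frame(antibody_id = ids, tag_seq = tags,
                         is_isotype_control = iso,
                         target_species = species,
                         stringsAsFactors = FALSE))
  })
}
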