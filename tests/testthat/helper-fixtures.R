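# Shared fixtures and independent brute-force oracles.

# -- oracles (kept independent of the package internals) ----------------------

# Hamming distance via integer codes, not the package's char-matrix path.
bf_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Exhaustive whitelist search: index of the unique nearest entry within
# max_hamming, NA on no match or tie at the minimal distance.
bf_correct <- function(query, seqs, max_hamming) {
  d <- vapply(seqs, bf_hamming, 0L, a = query)
  dm <- min(d)
  if (dm > max_hamming) return(NA_integer_)
  hits <- which(d == dm)
  if (length(hits) > 1L) NA_integer_ else hits
}

# Distinct-triple counting for exact UMI collapse.
bf_exact_collapse <- function(records) {
  key <- unique(paste(records$row, records$col, records$feature, records$umi,
                      sep = "|"))
  grp <- sub("\\|[^|]*$", "", key)
  tab <- table(grp)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  out <- data.frame(row = as.integer(vapply(parts, `[`, "", 1L)),
                    col = as.integer(vapply(parts, `[`, "", 2L)),
                    feature = vapply(parts, `[`, "", 3L),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$row, out$col, out$feature), ]
  rownames(out) <- NULL
  out
}

rand_dna_chr <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

# -- small shared fixtures ----------------------------------------------------

tiny_fixture_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "sc_tiny_fx")
      paths <- make_fixtures(dir, seed = 42L, scale = "small")
      cache <<- list(
        paths = paths,
        wlA = load_whitelist(paths$whitelist_a, "A"),
        wlB = load_whitelist(paths$whitelist_b, "B"),
        panel = load_panel(paths$panel),
        tx = generate_fixture_transcriptome(20L, seed = 44L),
        model = read_tissue_model(paths$tissue),
        layout = read_layout())
    }
    cache
  }
})

# A deterministic two-domain model over an n_rows x n_cols grid: the first
# `split_col` columns form domain "hot" where `hot_genes` are `fold`-fold
# enriched; everything else is "base".
two_domain_model <- function(n_rows, n_cols, split_col, gene_ids, ab_ids,
                             hot_genes = character(0),
                             hot_abs = character(0),
                             base_rna = 0.5, base_protein = 2, fold = 10,
                             background_rate = 0) {
  hot <- matrix(FALSE, n_rows, n_cols); hot[, seq_len(split_col)] <- TRUE
  mk_prof <- function(ids, base, hot_ids, hot_now) {
    v <- stats::setNames(rep(base, length(ids)), ids)
    if (hot_now) v[hot_ids] <- base * fold
    v
  }
  tissue_model(n_rows, n_cols, list(
    list(domain_id = "hot", mask = hot,
         rna_profile = mk_prof(gene_ids, base_rna, hot_genes, TRUE),
         protein_profile = mk_prof(ab_ids, base_protein, hot_abs, TRUE)),
    list(domain_id = "base", mask = !hot,
         rna_profile = mk_prof(gene_ids, base_rna, hot_genes, FALSE),
         protein_profile = mk_prof(ab_ids, base_protein, hot_abs, FALSE))),
    background_rate = background_rate)
}
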