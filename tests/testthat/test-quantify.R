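# Feature assignment, UMI collapse and matrix construction.

test_that("ADT tag matching corrects single errors and drops ties", {
  panel <- adt_panel(data.frame(
    antibody_id = c("CD3", "CD4"),
    tag_seq = c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC"),
    is_isotype_control = FALSE))
  expect_equal(match_adt_tag("AAAAAAAAAAAAAAAAAAA", panel), "CD3")
  # one substitution, nearest-unique
  expect_equal(match_adt_tag("AAAAAAAAAAAAAACAAAA", panel, max_hamming = 1L),
               "CD3")
  # constructed equidistant pair: d=1 from both tags
  tie_panel <- adt_panel(data.frame(
    antibody_id = c("x", "y"),
    tag_seq = c("AAAA", "AAAT"),
    is_isotype_control = FALSE))
  expect_true(is.na(match_adt_tag("AAACAA", tie_panel, max_hamming = 1L)))
  expect_error(match_adt_tag("AAA", tie_panel), "too short")
})

test_that("toy transcript assignment follows the unique-gene rule", {
  tx <- generate_fixture_transcriptome(5L, tx_length = 200L, seed = 3L)
  idx <- build_kmer_index(tx, k = 31L)
  # clean substring -> its gene
  expect_equal(assign_transcript_toy(substr(tx[["GENE002"]], 20, 109), idx),
               "GENE002")
  # verbatim shared sequence -> ambiguous, no match
  tx2 <- c(tx, GENEDUP = paste0("ACGT", tx[["GENE001"]]))
  idx2 <- build_kmer_index(tx2, k = 31L)
  expect_true(is.na(assign_transcript_toy(substr(tx[["GENE001"]], 10, 99), idx2)))
  # random sequence absent from the transcriptome -> no match
  set.seed(99)
  expect_true(all(is.na(assign_transcript_toy(rand_dna_chr(20L, 90L), idx))))
  # payload shorter than k -> no match
  expect_true(is.na(assign_transcript_toy("ACGTACGT", idx)))
})

test_that("exact UMI collapse counts distinct triples", {
  rec <- data.frame(row = c(1L, 1L, 1L, 2L),
                    col = c(1L, 1L, 1L, 3L),
                    feature = "CD3",
                    umi = c("AAAA", "AAAA", "AAAA", "AAAA"))
  out <- collapse_umis(rec, "exact")
  expect_equal(out$count, c(1L, 1L))  # same UMI in two pixels counts in each
  set.seed(17)
  n <- 10000L
  rnd <- data.frame(row = sample(1:5, n, TRUE), col = sample(1:5, n, TRUE),
                    feature = sample(c("a", "b", "c"), n, TRUE),
                    umi = rand_dna_chr(n, 4L))
  expect_equal(collapse_umis(rnd, "exact"), bf_exact_collapse(rnd))
})

test_that("directional collapse merges 1-mismatch children under the 2n-1 rule", {
  rec <- data.frame(row = 1L, col = 1L, feature = "CD3",
                    umi = c(rep("AAAA", 10), "AAAT"))
  expect_equal(collapse_umis(rec, "directional1mm")$count, 1L)
  expect_equal(collapse_umis(rec, "exact")$count, 2L)
  # counts 2 and 2: 2 >= 2*2-1 is false, so two molecules
  rec2 <- data.frame(row = 1L, col = 1L, feature = "CD3",
                     umi = rep(c("AAAA", "AAAT"), each = 2))
  expect_equal(collapse_umis(rec2, "directional1mm")$count, 2L)
})

test_that("collapse and matrix are invariant to record order", {
  set.seed(5)
  n <- 500L
  rec <- data.frame(row = sample(1:4, n, TRUE), col = sample(1:4, n, TRUE),
                    feature = sample(c("g1", "g2"), n, TRUE),
                    umi = rand_dna_chr(n, 5L))
  shuf <- rec[sample.int(n), ]
  for (mode in c("exact", "directional1mm"))
    expect_equal(collapse_umis(rec, mode), collapse_umis(shuf, mode))
  m1 <- build_matrix(collapse_umis(rec, "exact"), "RNA", grid = c(4L, 4L))
  m2 <- build_matrix(collapse_umis(shuf, "exact"), "RNA", grid = c(4L, 4L))
  expect_equal(m1$counts, m2$counts)
})

test_that("matrices keep panel zero-rows, label pixels row-x-col, police the grid", {
  panel <- generate_fixture_panel(273L, n_isotype = 9L, seed = 1L)
  empty <- data.frame(row = integer(0), col = integer(0),
                      feature = character(0), count = integer(0))
  m <- build_matrix(empty, "protein", features = panel$antibody_id,
                    grid = c(50L, 50L))
  expect_equal(dim(m), c(273L, 0L))
  one <- data.frame(row = 3L, col = 41L, feature = panel$antibody_id[1],
                    count = 2L)
  m1 <- build_matrix(one, "protein", features = panel$antibody_id,
                     grid = c(50L, 50L))
  expect_equal(colnames(m1$counts), "3x41")
  expect_equal(nrow(m1$counts), 273L)
  expect_error(build_matrix(transform(one, row = 51L), "protein",
                            features = panel$antibody_id, grid = c(50L, 50L)),
               "outside")
})

test_that("quantified totals never exceed passed demux records", {
  fx <- tiny_fixture_set()
  sim <- simulate_run(fx$model, fx$panel, fx$tx, list(A = fx$wlA, B = fx$wlB),
                      err = error_model(0.002, 2, seed = 6L),
                      out_dir = withr::local_tempdir())
  dm <- demux_library(sim$adt_r1, sim$adt_r2, fx$layout, fx$wlA, fx$wlB,
                      modality = "protein")
  rec <- dm$records
  rec$feature <- match_adt_tag(rec$payload, fx$panel)
  rec <- rec[!is.na(rec$feature), ]
  m <- build_matrix(collapse_umis(rec, "exact"), "protein",
                    features = fx$panel$antibody_id, grid = c(10L, 10L))
  expect_lte(sum(m$counts), dm$stats$passed)
})

test_that("counts recover the distinct-UMI truth across expression levels", {
  # Poisson means spanning 0.5 to 50; error-free run must match exactly
  fx <- tiny_fixture_set()
  genes <- names(fx$tx)[1:3]
  abs_ <- fx$panel$antibody_id[1:3]
  mk <- function(mu) stats::setNames(rep(mu, 3), genes)
  mkp <- function(mu) stats::setNames(rep(mu, 3), abs_)
  doms <- list(
    list(domain_id = "lo", mask = rbind(TRUE, FALSE, FALSE),
         rna_profile = mk(0.5), protein_profile = mkp(0.5)),
    list(domain_id = "mid", mask = rbind(FALSE, TRUE, FALSE),
         rna_profile = mk(5), protein_profile = mkp(5)),
    list(domain_id = "hi", mask = rbind(FALSE, FALSE, TRUE),
         rna_profile = mk(50), protein_profile = mkp(50)))
  model <- tissue_model(3L, 8L, lapply(doms, function(d) {
    d$mask <- matrix(rep(d$mask, 8L), nrow = 3L); d
  }))
  sim <- simulate_run(model, fx$panel, fx$tx, list(A = fx$wlA, B = fx$wlB),
                      err = error_model(0, 1, seed = 13L),
                      out_dir = withr::local_tempdir())
  dm <- demux_library(sim$adt_r1, sim$adt_r2, fx$layout, fx$wlA, fx$wlB,
                      modality = "protein")
  rec <- dm$records
  rec$feature <- match_adt_tag(rec$payload, fx$panel)
  m <- build_matrix(collapse_umis(rec, "exact"), "protein",
                    features = fx$panel$antibody_id, grid = c(3L, 8L))
  expect_equal(as.matrix(m$counts), as.matrix(sim$truth$adt_umi$counts))
  # with sequencing errors the recovered counts stay tightly correlated
  sim2 <- simulate_run(model, fx$panel, fx$tx, list(A = fx$wlA, B = fx$wlB),
                       err = error_model(0.005, 1, seed = 14L),
                       out_dir = withr::local_tempdir())
  dm2 <- demux_library(sim2$adt_r1, sim2$adt_r2, fx$layout, fx$wlA, fx$wlB,
                       modality = "protein")
  rec2 <- dm2$records
  rec2$feature <- match_adt_tag(rec2$payload, fx$panel)
  rec2 <- rec2[!is.na(rec2$feature), ]
  m2 <- build_matrix(collapse_umis(rec2, "exact"), "protein",
                     features = fx$panel$antibody_id, grid = c(3L, 8L))
  common <- intersect(colnames(m2$counts), colnames(sim2$truth$adt_umi$counts))
  r <- cor(as.vector(as.matrix(m2$counts[, common])),
           as.vector(as.matrix(sim2$truth$adt_umi$counts[, common])))
  expect_gte(r, 0.99)
})
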