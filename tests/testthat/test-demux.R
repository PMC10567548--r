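# Read-2 parsing, barcode correction, library demultiplexing.

test_that("parse_read2 inverts simulator assembly and rejects short reads", {
  layout <- read_layout()
  umi <- "ACGTACGTAC"; bcB <- "AAAACCCC"; bcA <- "GGGGTTTT"
  r2 <- paste0(umi, bcB, layout$linker_seq, bcA)
  parts <- parse_read2(r2, layout)
  expect_equal(parts$umi, umi)
  expect_equal(parts$bcB, bcB)
  expect_equal(parts$linker, layout$linker_seq)
  expect_equal(parts$bcA, bcA)
  # span 56 fits in a 60-nt read, a 50-nt read does not
  expect_silent(parse_read2(paste0(r2, "AAAA"), layout))
  expect_error(parse_read2(substr(r2, 1, 50), layout), "shorter")
})

test_that("correct_barcode resolves exact, 1-mismatch and ambiguous queries", {
  wl <- barcode_whitelist(c("AACCGGTT", "TTGGCCAA"), axis = "A")
  r <- correct_barcode("AACCGGTA", wl, max_hamming = 1L)
  expect_equal(as.integer(r), 1L)
  expect_equal(attr(r, "status"), "corrected")
  # exact match wins even with radius 0
  r0 <- correct_barcode("AACCGGTT", wl, max_hamming = 0L)
  expect_equal(as.integer(r0), 1L)
  expect_equal(attr(r0, "status"), "exact")
  # equidistant pair -> ambiguous, dropped
  suppressWarnings(wl2 <- barcode_whitelist(c("AAAA", "AAAT"), axis = "A"))
  ra <- correct_barcode("AAAC", wl2, max_hamming = 1L)
  expect_true(is.na(as.integer(ra)))
  expect_equal(attr(ra, "status"), "ambiguous")
  expect_error(correct_barcode("AAA", wl2), "length")
})

test_that("barcode correction agrees with exhaustive search on random queries", {
  wl <- generate_fixture_whitelists(50L, seed = 2L)$A
  set.seed(31)
  n <- 2000L
  queries <- rand_dna_chr(n, 8L)
  got <- as.integer(correct_barcode(queries, wl, max_hamming = 1L))
  want <- vapply(queries, bf_correct, 0L, seqs = wl$seq, max_hamming = 1L)
  expect_identical(got, unname(want))
})

test_that("error-free libraries demultiplex to the provenance log exactly", {
  fx <- tiny_fixture_set()
  sim <- simulate_run(fx$model, fx$panel, fx$tx, list(A = fx$wlA, B = fx$wlB),
                      err = error_model(0, 1, seed = 4L),
                      out_dir = withr::local_tempdir())
  dm <- demux_library(sim$adt_r1, sim$adt_r2, fx$layout, fx$wlA, fx$wlB,
                      modality = "protein")
  s <- dm$stats
  expect_equal(s$passed, s$total)
  expect_equal(s$total, s$short_read + s$fail_linker + s$fail_bcA +
                 s$fail_bcB + s$ambiguous + s$passed)
  prov <- sim$provenance[sim$provenance$modality == "protein", ]
  m <- merge(dm$records, prov, by = "read_id")
  expect_equal(nrow(m), nrow(prov))
  expect_identical(m$row.x, m$row.y)
  expect_identical(m$col.x, m$col.y)
  expect_identical(m$umi.x, m$umi.y)
})

test_that("correction is monotone in radius and never mis-assigns at min_dist >= 3", {
  fx <- tiny_fixture_set()
  expect_gte(attr(fx$wlA, "min_dist"), 3L)
  sim <- simulate_run(fx$model, fx$panel, fx$tx, list(A = fx$wlA, B = fx$wlB),
                      err = error_model(0.005, 1, seed = 12L),
                      out_dir = withr::local_tempdir())
  dm1 <- demux_library(sim$adt_r1, sim$adt_r2, fx$layout, fx$wlA, fx$wlB,
                       max_hamming_bc = 1L, modality = "protein")
  dm0 <- demux_library(sim$adt_r1, sim$adt_r2, fx$layout, fx$wlA, fx$wlB,
                       max_hamming_bc = 0L, modality = "protein")
  expect_gte(dm1$stats$passed, dm0$stats$passed)
  prov <- sim$provenance[sim$provenance$modality == "protein", ]
  m <- merge(dm1$records, prov, by = "read_id")
  expect_equal(sum(m$row.x != m$row.y | m$col.x != m$col.y), 0L)
})

test_that("linker and pairing gates fail the way they should", {
  layout <- read_layout()
  wlA <- barcode_whitelist(c("AACCGGTT", "TTGGCCAA"), axis = "A")
  wlB <- barcode_whitelist(c("ACACACAC", "GTGTGTGT"), axis = "B")
  umi <- "ACGTACGTAC"
  good <- paste0(umi, wlB$seq[1], layout$linker_seq, wlA$seq[1])
  bad_linker <- good
  substr(bad_linker, 19, 20) <- "CA"  # 2 linker mismatches (GT -> CA)
  dir <- withr::local_tempdir()
  r1 <- file.path(dir, "r1.fastq.gz"); r2 <- file.path(dir, "r2.fastq.gz")
  spatialcite:::.write_fastq_gz(c("a", "b"), c("ACGT", "ACGT"), r1)
  spatialcite:::.write_fastq_gz(c("a", "b"), c(good, bad_linker), r2)
  dm <- demux_library(r1, r2, layout, wlA, wlB, max_hamming_linker = 1L)
  expect_equal(dm$stats$passed, 1L)
  expect_equal(dm$stats$fail_linker, 1L)
  # mismatched mate ids abort with the record number
  spatialcite:::.write_fastq_gz(c("a", "zzz"), c("ACGT", "ACGT"), r1)
  expect_error(demux_library(r1, r2, layout, wlA, wlB), "record 2")
})
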