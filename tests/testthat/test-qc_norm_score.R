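# QC metrics, CLR/log normalization, signature scoring, pseudo-bulk.

make_counts <- function(mat, modality = "protein") {
  df <- expand.grid(f = seq_len(nrow(mat)), p = seq_len(ncol(mat)))
  counts <- data.frame(row = 1L, col = df$p,
                       feature = sprintf("F%02d", df$f),
                       count = as.integer(mat[cbind(df$f, df$p)]))
  build_matrix(counts, modality, features = sprintf("F%02d", seq_len(nrow(mat))),
               grid = c(1L, ncol(mat)))
}

test_that("qc metrics count UMIs and detected features per pixel", {
  m <- make_counts(cbind(c(0, 0, 5, 2), c(0, 0, 0, 0)))
  qc <- qc_metrics(m)
  expect_equal(qc$per_pixel$umi_count, c(7L, 0L))
  expect_equal(qc$per_pixel$feature_count, c(2L, 0L))
  expect_equal(qc$summary$mean_umi, 3.5)
  expect_equal(qc$summary$mean_features, 1)
  # invariance to pixel order is inherited from the fixed pixel ordering
  expect_equal(qc$per_pixel$pixel, c("1x1", "1x2"))
})

test_that("CLR reproduces the worked value and is zero-sum per pixel", {
  m <- make_counts(matrix(c(3, 0, 0), ncol = 1))
  y <- clr_normalize(m)$values[, 1]
  expect_equal(round(unname(y), 4), c(0.9242, -0.4621, -0.4621))
  # independent arithmetic: ln4 - mean(ln4, ln1, ln1)
  expect_equal(unname(y[1]), log(4) - mean(c(log(4), log(1), log(1))))
  m2 <- make_counts(matrix(c(1, 1, 1, 2, 0, 7), ncol = 2))
  expect_lt(max(abs(colSums(clr_normalize(m2)$values))), 1e-9)
  expect_equal(unname(clr_normalize(make_counts(matrix(c(1, 1, 1), ncol = 1)))$values[, 1]),
               c(0, 0, 0))
  # random matrices stay zero-sum
  set.seed(2)
  for (i in 1:5) {
    mm <- make_counts(matrix(rpois(40, 3), nrow = 5))
    expect_lt(max(abs(colSums(clr_normalize(mm)$values))), 1e-9)
  }
  # per-feature margin centres rows instead
  expect_lt(max(abs(rowSums(clr_normalize(m2, "per_feature")$values))), 1e-9)
  empty <- build_matrix(data.frame(row = integer(0), col = integer(0),
                                   feature = character(0), count = integer(0)),
                        "RNA", grid = c(1L, 1L))
  expect_error(clr_normalize(empty), "empty")
})

test_that("log-normalization is scale-invariant within a pixel and safe on zeros", {
  m <- make_counts(matrix(c(10, 0), ncol = 1), modality = "RNA")
  y <- lognorm_rna(m, scale = 10)$values[, 1]
  expect_equal(unname(y), c(log(11), 0))
  m2 <- make_counts(matrix(c(3, 7, 6, 14), ncol = 2), modality = "RNA")
  yy <- lognorm_rna(m2)$values
  expect_equal(yy[, 1], yy[, 2])  # doubling all counts changes nothing
  zed <- make_counts(matrix(c(0, 0), ncol = 1), modality = "RNA")
  expect_equal(unname(lognorm_rna(zed)$values[, 1]), c(0, 0))
})

test_that("signature scores are mean z-scores with the documented invariances", {
  set.seed(8)
  m <- make_counts(matrix(rpois(50, 5), nrow = 5))
  nm <- clr_normalize(m)
  one <- signature_score(nm, "F01")
  zs <- as.numeric(scale(nm$values["F01", ]))
  expect_equal(one$score, zs)
  # order and duplicates do not matter
  s1 <- signature_score(nm, c("F01", "F03", "F05"))
  s2 <- signature_score(nm, c("F05", "F01", "F03", "F01"))
  expect_equal(s1$score, s2$score)
  # constant feature is excluded from the mean
  vals <- nm$values; vals["F02", ] <- 1
  nm2 <- nm; nm2$values <- vals
  s3 <- signature_score(nm2, c("F01", "F02"))
  expect_equal(s3$score, signature_score(nm2, "F01")$score)
  expect_identical(attr(s3, "features_used"), "F01")
  expect_warning(signature_score(nm, c("F01", "NOPE")), "NOPE")
  expect_error(suppressWarnings(signature_score(nm, "NOPE")), "none")
})

test_that("pseudo-bulk sums pixels above the UMI filter", {
  m <- make_counts(cbind(c(1, 3), c(2, 4)))
  pb <- pseudobulk(m, min_total_umi = 0L)
  expect_equal(unname(pb$totals), c(3, 7))
  # a pixel with total 5 is excluded under the default filter of 10
  m2 <- make_counts(cbind(c(1, 4), c(12, 5)))
  pb2 <- pseudobulk(m2, min_total_umi = 10L)
  expect_equal(unname(pb2$totals), c(12, 5))
  expect_equal(pb2$n_pixels_used, 1L)
  # CLR of totals is centred
  expect_equal(sum(pb2$clr), 0)
})

test_that("pseudo-bulk of pipeline output matches pseudo-bulk of truth exactly", {
  fx <- tiny_fixture_set()
  sim <- simulate_run(fx$model, fx$panel, fx$tx, list(A = fx$wlA, B = fx$wlB),
                      err = error_model(0, 1, seed = 19L),
                      out_dir = withr::local_tempdir())
  dm <- demux_library(sim$adt_r1, sim$adt_r2, fx$layout, fx$wlA, fx$wlB,
                      modality = "protein")
  rec <- dm$records
  rec$feature <- match_adt_tag(rec$payload, fx$panel)
  m <- build_matrix(collapse_umis(rec, "exact"), "protein",
                    features = fx$panel$antibody_id, grid = c(10L, 10L))
  expect_equal(cor(pseudobulk(m)$totals, pseudobulk(sim$truth$adt_umi)$totals), 1)
})
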