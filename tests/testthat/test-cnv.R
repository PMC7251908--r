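test_that("expression preparation filters, standardizes, clips and orders", {
  vals <- rbind(
    low = rep(0.1, 12),                    # mean < 0.2 -> dropped
    const = rep(5, 12),                    # zero variance -> all-zero column
    spike = c(rep(1, 11), 100),            # extreme value -> clipped at 3
    ok = seq(0.5, 5, length.out = 12)
  )
  prep <- suppressWarnings(
    prep_from_values(vals, chrom = c("1", "1", "1", "1"),
                     params = cnv_params(window_genes = 2)))
  expect_false("low" %in% prep$genes$gene_name)
  expect_identical(unname(prep$matrix[prep$genes$gene_name == "const", ]),
                   rep(0, 12))
  expect_identical(max(prep$matrix), 3)
  expect_true(all(abs(prep$matrix) <= 3))
  # karyotype ordering: chromosome 2 precedes 10 precedes X
  vals2 <- matrix(seq(1, 4, length.out = 3 * 8), nrow = 3, byrow = TRUE)
  vals2 <- vals2 + rep(c(0, 1, 2), times = 8)[seq_len(24)]
  prep2 <- prep_from_values(matrix(runif(3 * 8, 1, 5), 3, 8),
                            chrom = c("X", "10", "2"),
                            params = cnv_params(window_genes = 1))
  expect_identical(prep2$genes$chromosome, c("2", "10", "X"))
  expect_error(prep_from_values(matrix(runif(40, 1, 5), 4, 10),
                                chrom = rep("1", 4)),
               "fewer than")
})

test_that("moving average equals the naive window loop", {
  # 10-gene toy chromosome, window 3, hand-checkable
  set.seed(2)
  vals <- matrix(runif(10 * 4, 1, 6), nrow = 10)
  prep <- prep_from_values(vals, chrom = rep("1", 10),
                           params = cnv_params(window_genes = 3))
  sm <- moving_average(prep)
  expect_lt(max(abs(sm$matrix -
                      naive_moving_average(prep$matrix, prep$genes$chromosome, 3))),
            1e-12)
  # larger multi-chromosome case, window 7
  vals <- matrix(runif(60 * 5, 1, 6), nrow = 60)
  chrom <- rep(c("1", "2", "3"), each = 20)
  prep <- prep_from_values(vals, chrom = chrom,
                           params = cnv_params(window_genes = 7))
  sm <- moving_average(prep)
  expect_lt(max(abs(sm$matrix -
                      naive_moving_average(prep$matrix, prep$genes$chromosome, 7))),
            1e-12)
})

test_that("windowing respects identities and never spans chromosomes", {
  set.seed(3)
  vals <- matrix(runif(40 * 6, 1, 6), nrow = 40)
  chrom <- rep(c("1", "2"), each = 20)
  # window of 1 is the per-cell re-centered input
  prep <- prep_from_values(vals, chrom, cnv_params(window_genes = 1))
  sm <- moving_average(prep)
  expect_equal(sm$matrix, sweep(prep$matrix, 2, colMeans(prep$matrix)),
               tolerance = 1e-12)
  # per-cell mean is zero after re-centering
  prep5 <- prep_from_values(vals, chrom, cnv_params(window_genes = 5))
  sm5 <- moving_average(prep5)
  expect_equal(unname(colMeans(sm5$matrix)), rep(0, 6), tolerance = 1e-12)
  # permuting chromosome blocks permutes output blocks identically
  perm_vals <- rbind(vals[21:40, ], vals[1:20, ])
  prep_p <- prep_from_values(perm_vals, rep(c("1", "2"), each = 20),
                             cnv_params(window_genes = 5))
  sm_p <- moving_average(prep_p)
  expect_equal(unname(sm_p$matrix),
               unname(rbind(sm5$matrix[21:40, ], sm5$matrix[1:20, ])),
               tolerance = 1e-12)
  # all-zero input stays all-zero
  z <- prep5; z$matrix[] <- 0
  expect_identical(unique(as.numeric(moving_average(z)$matrix)), 0)
})

test_that("the CNV score is the mean of squared inferred values", {
  expect_equal(cnv_score(c(0.1, -0.1, 0.2)), 0.02)
  expect_identical(cnv_score(rep(0, 5)), 0)
  v <- c(0.3, -0.2, 0.05)
  expect_equal(cnv_score(3 * v), 9 * cnv_score(v))
  m <- cbind(v, 2 * v)
  expect_equal(unname(cnv_score(m)), c(cnv_score(v), 4 * cnv_score(v)))
})

test_that("the two-cutoff call rule is exhaustive, boundaries undetermined", {
  params <- cnv_params()  # cutoffs 0.02 and 0.2
  score <- c(0.03, 0.01, 0.03, 0.01, 0.02, 0.03, 0.01, 0.02, 0.02)
  corr <- c(0.50, 0.10, 0.10, 0.50, 0.50, 0.20, 0.20, 0.20, 0.10)
  expect_identical(
    cnv_call_rule(score, corr, params),
    c("tumor",         # both above
      "non-tumor",     # both below
      "undetermined",  # score above, correlation below
      "undetermined",  # score below, correlation above
      "undetermined",  # score exactly at cutoff
      "undetermined",  # correlation exactly at cutoff
      "undetermined",  # score below, correlation at cutoff
      "undetermined",  # both exactly at cutoffs
      "undetermined")  # score at cutoff, correlation below
  )
  expect_identical(cnv_call_rule(0.5, NA_real_, params), "undetermined")
})

test_that("recalibration zeroes the non-tumor baseline and keeps the signal", {
  p <- default_processed()
  res <- default_cnv()$result
  expect_true(res$recalibrated)
  # the cells used as the recalibration reference average to zero per gene
  nt <- colnames(res$matrix) %in% res$baseline_barcodes
  expect_gt(sum(nt), 0)
  expect_equal(max(abs(rowMeans(res$matrix[, nt, drop = FALSE]))), 0,
               tolerance = 1e-10)
  # planted gain: recalibrated tumor mean positive over the gained segment,
  # near zero over neutral segments (sign check against the planted truth)
  truth <- p$sim$truth
  dosage <- p$sim$gene_dosage
  gained <- res$genes$gene_id %in% dosage$gene_id[dosage$dosage == 1.5]
  neutral <- res$genes$gene_id %in% dosage$gene_id[dosage$dosage == 1] &
    !res$genes$chromosome %in% "MT"
  tum_mean <- rowMeans(res$matrix[, res$calls$call == "tumor", drop = FALSE])
  expect_gt(mean(tum_mean[gained]), 0.1)
  expect_lt(abs(mean(tum_mean[neutral])), 0.1)
  expect_gt(mean(tum_mean[gained]), mean(tum_mean[neutral]))
})

test_that("identical cells recalibrate to all-zero and constant references warn", {
  vals <- matrix(rep(seq(1, 5, length.out = 30), 8), nrow = 30)
  prep <- prep_from_values(vals, rep("1", 30), cnv_params(window_genes = 5))
  sm <- moving_average(prep)
  # identical cells: z-scores are zero/0-variance, matrix all zero
  expect_warning(res <- malignancy_call(sm), "constant")
  expect_true(all(res$calls$call == "undetermined"))
  expect_warning(rec <- recalibrate(res), "no non-tumor")
  expect_false(rec$recalibrated)
})

test_that("reference profile tracks the planted dosage profile", {
  p <- default_processed()
  res <- default_cnv()$result
  dosage <- p$sim$gene_dosage
  d <- log2(dosage$dosage[match(res$genes$gene_id, dosage$gene_id)])
  keep <- !is.na(d)
  # window-smooth the planted log2 profile the same way
  smooth_d <- naive_moving_average(matrix(d[keep], ncol = 1),
                                   res$genes$chromosome[keep],
                                   res$params$window_genes)
  expect_gte(cor(res$reference[keep], smooth_d[, 1]), 0.6)
})
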