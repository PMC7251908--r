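test_that("TPM-like normalization matches its stated arithmetic", {
  exp <- toy_experiment(matrix(c(1, 3), nrow = 2))
  exp <- normalize_tpm(exp)
  # counts [1,3], depth 4 -> pre-log [250000, 750000]
  expect_equal(as.numeric(exp$norm[, 1]),
               log2(1 + c(250000, 750000)))
  # zero count stays zero after the log transform
  exp2 <- normalize_tpm(toy_experiment(matrix(c(0, 5), nrow = 2)))
  expect_identical(exp2$norm[1, 1], 0)
  # doubling all counts in a cell leaves the normalized vector unchanged
  a <- normalize_tpm(toy_experiment(matrix(c(2, 6, 1), nrow = 3)))
  b <- normalize_tpm(toy_experiment(matrix(c(4, 12, 2), nrow = 3)))
  expect_equal(as.numeric(a$norm), as.numeric(b$norm))
  # pre-log values sum to the scale factor in every cell
  p <- default_processed()
  pre_log <- 2^as.matrix(p$exp$norm) - 1
  expect_equal(unname(colSums(pre_log)), rep(1e6, ncol(pre_log)))
  expect_error(normalize_tpm(toy_experiment(matrix(c(0, 0), nrow = 2))),
               "zero-depth")
})

test_that("gene prevalence filter uses an inclusive 1% threshold", {
  counts <- matrix(0, nrow = 3, ncol = 200)
  counts[1, ] <- 1          # in every cell
  counts[2, 1:2] <- 1       # exactly 2/200 = 1%
  counts[3, ] <- 0          # nowhere
  counts[1, ] <- counts[1, ] + 1  # keep depth positive
  exp <- toy_experiment(counts)
  out <- gene_prevalence_filter(exp)
  expect_identical(out$genes$gene_name, c("G1", "G2"))
  expect_warning(gene_prevalence_filter(toy_experiment(matrix(1, 2, 10))),
                 "degenerate")
})

test_that("variable-gene selection is dispersion-driven and order-invariant", {
  set.seed(1)
  n <- 120
  vals <- rbind(
    constant = rep(3, n),
    low_disp = 3 + rnorm(n, sd = 0.05),
    high_disp = 3 + rnorm(n, sd = 2.5),
    mid1 = 3 + rnorm(n, sd = 0.1), mid2 = 3 + rnorm(n, sd = 0.1),
    mid3 = 3 + rnorm(n, sd = 0.1), mid4 = 3 + rnorm(n, sd = 0.1)
  )
  exp <- toy_norm_experiment(abs(vals))
  sel <- select_variable_genes(exp, n_bins = 1, dispersion_cutoff = 1)
  expect_true(exp$genes$gene_id[3] %in% sel)       # high dispersion selected
  expect_false(exp$genes$gene_id[1] %in% sel)      # constant gene never
  perm <- sample(n)
  exp_perm <- toy_norm_experiment(abs(vals)[, perm])
  expect_identical(select_variable_genes(exp_perm, n_bins = 1,
                                         dispersion_cutoff = 1), sel)
})

test_that("two separated populations cluster perfectly and deterministically", {
  sim <- two_pop_sim()
  exp <- suppressWarnings(normalize_tpm(gene_prevalence_filter(sim$experiment)))
  cl <- reduce_and_cluster(exp, seed = 5)
  expect_identical(dplyr::n_distinct(cl$clusters$cluster), 2L)
  expect_equal(mclust::adjustedRandIndex(cl$clusters$cluster,
                                         sim$truth$cell_type), 1)
  cl2 <- reduce_and_cluster(exp, seed = 5)
  expect_identical(cl$clusters, cl2$clusters)
  # PCA loadings are orthonormal
  expect_equal(crossprod(cl$pc_scores / rep(sqrt(colSums(cl$pc_scores^2)),
                                            each = nrow(cl$pc_scores)))[1, 2],
               0, tolerance = 1e-10)
  expect_error(reduce_and_cluster(keep_cells(exp, exp$cells$barcode[1:10])),
               "n_pcs")
})

test_that("cluster + marker annotation recovers the four default cell types", {
  p <- default_processed()
  cl <- reduce_and_cluster(p$exp, seed = 5)
  ann <- suppressWarnings(
    annotate_clusters(p$exp, cl, default_marker_genes()[
      c("tumor", "stromal", "fibroblast", "macrophage")]))
  lab <- dplyr::left_join(cl$clusters, ann[, c("cluster", "cell_type")],
                          by = "cluster")
  truth <- p$sim$truth[match(lab$barcode, p$sim$truth$barcode), ]
  expect_gte(mclust::adjustedRandIndex(lab$cell_type, truth$cell_type), 0.9)
})

test_that("marker annotation follows the arg-max with alphabetical ties", {
  vals <- rbind(A1 = c(5, 5, 0, 0), B1 = c(0, 0, 5, 5))
  exp <- toy_norm_experiment(vals, gene_names = c("A1", "B1"))
  clusters <- tibble::tibble(barcode = paste0("cell", 1:4),
                             cluster = rep(c("C1", "C2"), each = 2))
  ann <- annotate_clusters(exp, clusters, list(typeA = "A1", typeB = "B1"))
  expect_identical(ann$cell_type[ann$cluster == "C1"], "typeA")
  expect_identical(ann$cell_type[ann$cluster == "C2"], "typeB")
  expect_warning(
    tie <- annotate_clusters(exp, clusters,
                             list(zeta = "A1", alpha = "A1", typeB = "B1")),
    "tie")
  expect_identical(tie$cell_type[tie$cluster == "C1"], "alpha")
  expect_error(suppressWarnings(annotate_clusters(exp, clusters,
                                                  list(x = "NOPE"))),
               "marker")
})

test_that("the DE t statistic matches the closed-form Welch formula", {
  p <- default_processed()
  exp <- p$exp
  truth <- p$sim$truth
  tum <- intersect(truth$barcode[truth$cell_type == "tumor"],
                   exp$cells$barcode)[1:3]
  str <- intersect(truth$barcode[truth$cell_type == "stromal"],
                   exp$cells$barcode)[1:3]
  de <- differential_expression(exp, tum, str, min_fraction = 0,
                                min_logfc = 0)
  m <- as.matrix(exp$norm)
  for (g in de$gene_id[c(1, 50, 500)]) {
    a <- m[match(g, exp$genes$gene_id), match(tum, exp$cells$barcode)]
    b <- m[match(g, exp$genes$gene_id), match(str, exp$cells$barcode)]
    t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
    row <- de[de$gene_id == g, ]
    expect_equal(row$statistic, t_hand, tolerance = 1e-12)
    expect_equal(row$logfc, mean(a) - mean(b), tolerance = 1e-12)
  }
})

test_that("DE null and extreme cases behave as the t test dictates", {
  vals <- rbind(
    same = rep(4, 100),
    strong = c(rep(5, 50), rep(0, 50)) + 0.001 * (1:100 %% 7)
  )
  exp <- toy_norm_experiment(vals)
  a <- exp$cells$barcode[1:50]; b <- exp$cells$barcode[51:100]
  de <- differential_expression(exp, a, b, min_fraction = 0, min_logfc = 0)
  expect_identical(de$statistic[de$gene_name == "same"], 0)
  expect_identical(de$p.value[de$gene_name == "same"], 1)
  expect_lt(de$p.value[de$gene_name == "strong"], 1e-10)
  expect_error(differential_expression(exp, a, a), "disjoint")
  # highlight flag reproduces the volcano rule |logFC| > 0.8 & p < 0.001
  expect_true(de$highlight[de$gene_name == "strong"])
  expect_false(de$highlight[de$gene_name == "same"])
})
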