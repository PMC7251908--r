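test_that("fixed seed reproduces byte-identical matrices", {
  cfg <- sim_config(n_cells_per_type = c(tumor = 30, fibroblast = 30),
                    seed = 5)
  a <- simulate_mixed_pdx(cfg)
  b <- simulate_mixed_pdx(cfg)
  expect_identical(as.matrix(a$experiment$counts), as.matrix(b$experiment$counts))
  expect_identical(a$truth, b$truth)
})

test_that("without contamination or multiplets every barcode is single-genome", {
  cfg <- sim_config(n_cells_per_type = c(tumor = 40, fibroblast = 40),
                    ambient_cross_species_rate = 0, multiplet_rate = 0,
                    lr_pairs_planted = NULL, seed = 6)
  sim <- simulate_mixed_pdx(cfg)
  human <- sim$experiment$genes$genome == "GRCh38"
  h_umis <- Matrix::colSums(sim$experiment$counts[human, ])
  m_umis <- Matrix::colSums(sim$experiment$counts[!human, ])
  expect_true(all((h_umis == 0) != (m_umis == 0)))
  # and species assignment then recovers the truth for every barcode
  sp <- suppressWarnings(assign_species(sim$experiment))
  expect_identical(sp$species, sim$truth$species)
})

test_that("neutral dosage leaves tumor and normal cells exchangeable", {
  seg <- data.frame(chromosome = "1", start_gene = 1L, end_gene = 150L,
                    dosage = 1, subclone = "c1")
  cfg <- sim_config(n_cells_per_type = c(tumor = 300, stromal = 300),
                    cell_type_species = c(tumor = "human", stromal = "human"),
                    cnv_segments = seg, cycle_program_strength = 1,
                    ambient_cross_species_rate = 0, multiplet_rate = 0,
                    lr_pairs_planted = NULL, seed = 8)
  sim <- simulate_mixed_pdx(cfg)
  exp <- sim$experiment
  filler <- startsWith(exp$genes$gene_name, "GH") & exp$genes$chromosome %in% "1"
  tum <- sim$truth$malignant
  mu_t <- Matrix::rowMeans(exp$counts[filler, tum])
  mu_n <- Matrix::rowMeans(exp$counts[filler, !tum])
  # identical NB laws: per-gene mean ratio concentrates at 1
  expect_equal(sum(mu_t) / sum(mu_n), 1, tolerance = 0.05)
})

test_that("a planted dosage multiplies expected counts by that dosage", {
  # 500 tumor vs 500 normal cells; dosage 1.5 over genes 1-150 of chromosome 1
  sim <- default_sim()
  exp <- sim$experiment
  truth <- sim$truth
  gained <- sim$gene_dosage$gene_id[sim$gene_dosage$dosage == 1.5]
  filler <- exp$genes$gene_id %in% gained & startsWith(exp$genes$gene_name, "GH")
  tum <- truth$barcode[truth$malignant & truth$species == "human"]
  nor <- truth$barcode[!truth$malignant & truth$species == "human"]
  it <- match(tum, exp$cells$barcode); ino <- match(nor, exp$cells$barcode)
  ratio <- sum(exp$counts[filler, it]) / length(it) /
    (sum(exp$counts[filler, ino]) / length(ino))
  # analytic NB expectation: ratio of means = dosage
  expect_equal(ratio, 1.5, tolerance = 0.08)
  # monotone in dosage: the lost segment sits below neutral, below gained
  lost <- sim$gene_dosage$gene_id[sim$gene_dosage$dosage == 0.5]
  fl <- exp$genes$gene_id %in% lost & startsWith(exp$genes$gene_name, "GH")
  ratio_lost <- sum(exp$counts[fl, it]) / length(it) /
    (sum(exp$counts[fl, ino]) / length(ino))
  expect_lt(ratio_lost, 1)
  expect_lt(ratio_lost, ratio)
})

test_that("overlapping CNV segments within a subclone are rejected", {
  seg <- data.frame(chromosome = c("1", "1"), start_gene = c(1L, 100L),
                    end_gene = c(120L, 180L), dosage = c(1.5, 0.5),
                    subclone = "c1")
  expect_error(sim_config(cnv_segments = seg), "overlap")
  # the same segments on different subclones are fine
  seg$subclone <- c("c1", "c2")
  expect_s3_class(sim_config(cnv_segments = seg), "scpdx_sim_config")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(multiplet_rate = 1.2), "rates")
  expect_error(sim_config(cnv_segments = data.frame(
    chromosome = "1", start_gene = 1L, end_gene = 10L, dosage = -1,
    subclone = "c1")), "dosage")
  expect_error(sim_config(cell_type_species = c(tumor = "human")),
               "species")
  # marker gene in both genomes
  mk <- default_marker_genes()
  mk$fibroblast[1] <- mk$tumor[1]
  expect_error(sim_config(marker_genes = mk), "exactly one genome")
})

test_that("fixture round-trips through MatrixMarket exactly", {
  sim <- simulate_mixed_pdx(sim_config(
    n_cells_per_type = c(tumor = 20, fibroblast = 20), seed = 9))
  dir <- withr::local_tempdir()
  write_fixture(sim$experiment, dir, truth = sim$truth)
  back <- read_pdx_matrix(dir)
  expect_equal(as.matrix(back$counts),
               as.matrix(sim$experiment$counts), ignore_attr = TRUE)
  # conservation through I/O
  expect_equal(Matrix::colSums(back$counts),
               Matrix::colSums(sim$experiment$counts), ignore_attr = TRUE)
  expect_equal(Matrix::rowSums(back$counts),
               Matrix::rowSums(sim$experiment$counts), ignore_attr = TRUE)
  expect_identical(back$genes$genome, sim$experiment$genes$genome)
  truth_back <- readr::read_csv(file.path(dir, "truth.csv"),
                                show_col_types = FALSE)
  expect_identical(truth_back$species, sim$truth$species)
})

test_that("fixture writer handles degenerate and toy matrices", {
  empty <- toy_experiment(matrix(0L, nrow = 4, ncol = 0))
  dir <- withr::local_tempdir()
  write_fixture(empty, dir)
  header <- readLines(file.path(dir, "matrix.mtx"), n = 3)
  expect_match(header[1], "MatrixMarket")
  back <- read_pdx_matrix(dir)
  expect_identical(dim(back$counts), c(4L, 0L))

  toy <- toy_experiment(matrix(c(1, 0, 2, 0, 0, 3, 0, 0, 0, 4, 5, 6), 4, 3))
  dir2 <- withr::local_tempdir()
  write_fixture(toy, dir2)
  lines <- readLines(file.path(dir2, "matrix.mtx"))
  dims <- strsplit(trimws(lines[grep("^%", lines, invert = TRUE)[1]]), "\\s+")[[1]]
  expect_identical(as.integer(dims), c(4L, 3L, 6L))
})
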