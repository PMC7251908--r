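# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

# The default study conditions: ~2000 cells, 4 types, one tumor subclone with
# 30% of human genes at dosage 0.5/1.5.
default_sim <- function() {
  cached("default_sim", function() suppressWarnings(
    simulate_mixed_pdx(sim_config(seed = 101))
  ))
}

# default sim taken through species assignment, QC, prevalence filter and
# normalization
default_processed <- function() {
  cached("default_processed", function() {
    sim <- default_sim()
    sp <- assign_species(sim$experiment)
    qc <- filter_cells(sim$experiment, species = sp)
    exp <- suppressWarnings(normalize_tpm(gene_prevalence_filter(qc$experiment)))
    list(exp = exp, species = sp, qc = qc, sim = sim)
  })
}

# full malignancy-calling chain on the default data, as the pipeline runs it:
# cluster, annotate with markers, anchor the CNV baseline on the non-tumor
# human cells, infer and recalibrate
default_cnv <- function() {
  cached("default_cnv", function() {
    p <- default_processed()
    cl <- reduce_and_cluster(p$exp, seed = 5)
    ann <- suppressWarnings(annotate_clusters(p$exp, cl, default_marker_genes()[
      c("tumor", "stromal", "fibroblast", "macrophage")]))
    lab <- dplyr::left_join(cl$clusters, ann[, c("cluster", "cell_type")],
                            by = "cluster")
    human <- intersect(p$species$barcode[p$species$species == "human"],
                       p$exp$cells$barcode)
    hexp <- keep_genes(keep_cells(p$exp, human),
                       p$exp$genes$gene_id[p$exp$genes$genome == "GRCh38"])
    baseline <- intersect(lab$barcode[lab$cell_type != "tumor"], human)
    res <- suppressWarnings(infer_cnv(hexp, baseline_cells = baseline))
    list(result = res, baseline = baseline, labels = lab)
  })
}

# a small clean two-type human-only mixture with no CNV, no cycle
# heterogeneity and no contamination
two_pop_sim <- function() {
  cached("two_pop_sim", function() {
    cfg <- sim_config(
      n_cells_per_type = c(tumor = 150, stromal = 150),
      cell_type_species = c(tumor = "human", stromal = "human"),
      cnv_segments = data.frame(chromosome = character(),
                                start_gene = integer(), end_gene = integer(),
                                dosage = numeric(), subclone = character()),
      cycle_program_strength = 1,
      ambient_cross_species_rate = 0, multiplet_rate = 0,
      lr_pairs_planted = NULL, seed = 33
    )
    suppressWarnings(simulate_mixed_pdx(cfg))
  })
}

# build a pdx_experiment directly from a dense counts matrix
toy_experiment <- function(counts, genome = "GRCh38", gene_names = NULL,
                           chromosome = NULL, start = NULL) {
  n_g <- nrow(counts)
  if (is.null(gene_names)) {
    gene_names <- rownames(counts) %||% paste0("G", seq_len(n_g))
  }
  genes <- tibble::tibble(
    gene_id = paste0("ID", seq_len(n_g)), gene_name = gene_names,
    genome = rep_len(genome, n_g)
  )
  if (!is.null(chromosome)) {
    genes$chromosome <- as.character(chromosome)
    genes$start <- as.integer(start %||% seq_len(n_g))
  }
  pdx_experiment(counts, genes,
                 tibble::tibble(barcode = sprintf("cell%d",
                                                  seq_len(ncol(counts)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalized toy experiment straight from a value matrix (norm slot injected,
# bypassing count normalization, for operations defined on normalized values)
toy_norm_experiment <- function(values, ...) {
  counts <- matrix(1, nrow(values), ncol(values))
  rownames(counts) <- rownames(values)
  exp <- toy_experiment(counts, ...)
  exp$norm <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  dimnames(exp$norm) <- dimnames(exp$counts)
  exp
}
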