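# literal re-implementation of the windowing used as an independent oracle:
# per chromosome, per cell, mean over the window of `w` genes centered on
# each gene (truncated at the ends), then per-cell re-centering
naive_moving_average <- function(z, chrom, w) {
  out <- z * NA
  for (cell in seq_len(ncol(z))) {
    for (ch in unique(chrom)) {
      rows <- which(chrom == ch)
      g <- length(rows)
      for (k in seq_len(g)) {
        lo <- max(1, k - floor((w - 1) / 2))
        hi <- min(g, k + ceiling((w - 1) / 2))
        out[rows[k], cell] <- mean(z[rows[lo:hi], cell])
      }
    }
  }
  sweep(out, 2, colMeans(out))
}

prep_from_values <- function(vals, chrom, params = cnv_params()) {
  exp <- toy_norm_experiment(vals, chromosome = chrom,
                             start = stats::ave(seq_along(chrom), chrom,
                                                FUN = seq_along))
  prepare_expression(exp, params = params)
}

# fixture with one planted violation of each QC rule, built by hand so the
# expected removal counts are known exactly
planted_qc_fixture <- function() {
  h_names <- c(paste0("HG", 1:588), "ACTB", "GAPDH",
               paste0("MT-", c("ND1", "ND2", "ND3", "ND4", "ND5", "ND6",
                               "CO1", "CO2", "CO3", "CYB")))
  m_names <- c(paste0("MG", 1:98), "Actb", "Gapdh")
  make_cell <- function(filler, hk, mito_total, mouse_total = 0) {
    h <- numeric(600)
    h[seq_along(filler)] <- filler
    h[589:590] <- hk
    h[591:600] <- rep(mito_total / 10, 10)
    m <- numeric(100)
    if (mouse_total > 0) m[seq_len(mouse_total)] <- 1
    c(h, m)
  }
  cells <- cbind(
    pass          = make_cell(rep(8, 550), c(100, 100), 240),
    umi_boundary  = make_cell(rep(1, 500), c(230, 230), 40),    # exactly 1000
    umi_lo_fail   = make_cell(rep(1, 500), c(220, 229), 50),    # 999
    umi_hi_fail   = make_cell(rep(270, 588), c(500, 500), 1000),# 161760
    genes_fail    = make_cell(rep(2, 487), c(100, 100), 60),    # 499 genes
    mito_fail     = make_cell(rep(8, 550), c(100, 100), 600),   # 11.5% mito
    hk_fail       = make_cell(rep(8, 550), c(0, 0), 240),
    mult_fail     = make_cell(rep(1, 500), c(220, 220), 50, mouse_total = 10),
    mult_pass     = make_cell(rep(1, 500), c(222, 223), 50, mouse_total = 5)
  )
  genes <- tibble::tibble(
    gene_id = paste0("ID", 1:700),
    gene_name = c(h_names, m_names),
    genome = c(rep("GRCh38", 600), rep("mm10", 100))
  )
  pdx_experiment(cells, genes, tibble::tibble(barcode = colnames(cells)))
}

lr_toy <- function() {
  # 5 tumor cells (3 express the ligand), 4 T cells (2 express the receptor)
  vals <- rbind(
    CD274 = c(2, 3, 1, 0, 0, 0, 0, 0.5, 0),
    PDCD1 = c(0, 0, 0, 0, 0, 4, 2, 0, 0),
    OTHER = rep(1, 9)
  )
  exp <- toy_norm_experiment(vals, gene_names = rownames(vals))
  types <- tibble::tibble(barcode = exp$cells$barcode,
                          cell_type = c(rep("tumor", 5), rep("tcell", 4)))
  list(exp = exp, types = types)
}

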