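#' Cell-level quality-control parameters
#'
#' Thresholds for droplet QC and human/mouse demultiplexing: UMI bounds,
#' expressed-gene bounds, mitochondrial UMI fraction, a minimum mean
#' housekeeping expression (beta-actin and GAPDH, on the log2(TPM-like + 1)
#' scale), the cross-species fraction at which a barcode is called a
#' multiplet, and the stricter expressed-gene floor applied to tumor
#' clusters.
#'
#' @param umi_min,umi_max retained barcodes satisfy umi_min <= UMIs <= umi_max
#' @param genes_min,genes_max bounds on expressed genes (count >= 1)
#' @param mito_fraction_max maximum mitochondrial UMI fraction
#' @param housekeeping_genes the two housekeeping gene names (human symbols)
#' @param housekeeping_genes_mouse mouse counterparts, used for cells whose
#'   species label is mouse
#' @param housekeeping_min_mean minimum mean housekeeping expression,
#'   log2(TPM-like + 1) scale
#' @param cross_species_fraction minority-genome UMI fraction at or above
#'   which a barcode is a multiplet
#' @param tumor_cluster_genes_min tumor cells must exceed this many expressed
#'   genes (strict \code{>})
#' @param mito_pattern regex on gene names identifying mitochondrial genes
#' @return a `scpdx_qc_params` list
#' @export
qc_params <- function(umi_min = 1000, umi_max = 150000,
                      genes_min = 500, genes_max = 10000,
                      mito_fraction_max = 0.10,
                      housekeeping_genes = c("ACTB", "GAPDH"),
                      housekeeping_genes_mouse = c("Actb", "Gapdh"),
                      housekeeping_min_mean = 3,
                      cross_species_fraction = 0.01,
                      tumor_cluster_genes_min = 2000,
                      mito_pattern = "^(MT-|mt-)") {
  stopifnot(umi_min < umi_max, genes_min < genes_max,
            mito_fraction_max >= 0, mito_fraction_max <= 1,
            cross_species_fraction >= 0, cross_species_fraction <= 1,
            length(housekeeping_genes) == 2)
  structure(
    list(umi_min = umi_min, umi_max = umi_max, genes_min = genes_min,
         genes_max = genes_max, mito_fraction_max = mito_fraction_max,
         housekeeping_genes = housekeeping_genes,
         housekeeping_genes_mouse = housekeeping_genes_mouse,
         housekeeping_min_mean = housekeeping_min_mean,
         cross_species_fraction = cross_species_fraction,
         tumor_cluster_genes_min = tumor_cluster_genes_min,
         mito_pattern = mito_pattern),
    class = "scpdx_qc_params"
  )
}

species_umis <- function(exp) {
  genome <- exp$genes$genome
  human <- genome %in% c("GRCh38", "hg38", "hg19", "human")
  mouse <- genome %in% c("mm10", "mm39", "mouse")
  if (!any(human) && !any(mouse)) abort("features carry no recognised genome tag")
  tibble(
    barcode = exp$cells$barcode,
    human_umis = as.numeric(Matrix::colSums(exp$counts[human, , drop = FALSE])),
    mouse_umis = as.numeric(Matrix::colSums(exp$counts[mouse, , drop = FALSE]))
  )
}

#' Assign each barcode to human, mouse, or multiplet
#'
#' The majority genome defines the candidate species; a barcode whose
#' minority-genome UMI fraction is at or above `cross_species_fraction`
#' (default 1%) is called a multiplet.
#'
#' @param exp a [pdx_experiment()] whose features carry genome tags
#' @param params a [qc_params()]
#' @return tibble (barcode, human_umis, mouse_umis, minority_fraction,
#'   species)
#' @export
assign_species <- function(exp, params = qc_params()) {
  su <- species_umis(exp)
  total <- su$human_umis + su$mouse_umis
  if (any(total == 0)) abort("every barcode must have at least one count")
  if (all(su$mouse_umis == 0) || all(su$human_umis == 0)) {
    only <- if (all(su$mouse_umis == 0)) "human" else "mouse"
    warn(paste0("matrix contains a single genome; all barcodes labeled ", only))
    return(mutate(su, minority_fraction = 0, species = only))
  }
  su %>%
    mutate(
      minority_fraction = pmin(.data$human_umis, .data$mouse_umis) / total,
      species = dplyr::case_when(
        .data$minority_fraction >= params$cross_species_fraction ~ "multiplet",
        .data$human_umis >= .data$mouse_umis ~ "human",
        TRUE ~ "mouse"
      )
    )
}

#' Apply the cell-level quality filters
#'
#' Retains barcodes satisfying all of: UMI bounds, expressed-gene bounds,
#' mitochondrial fraction, and mean housekeeping expression (computed on
#' each cell's own log2(TPM-like + 1) values) at or above the floor.
#' Multiplets are expected to have been removed beforehand via
#' [assign_species()]; if a `species` table is given, multiplet barcodes are
#' removed here first. Removal attribution uses the fixed rule order
#' multiplet, umi, genes, mito, housekeeping (first failing rule), but the
#' retained set is the conjunction of all predicates and so order-free.
#'
#' @inheritParams assign_species
#' @param species optional output of [assign_species()]
#' @return list with `experiment` (filtered) and `report`, a
#'   `scpdx_qc_report` tibble (barcode, umis, n_genes, mito_fraction,
#'   housekeeping_mean, retained, rule)
#' @export
filter_cells <- function(exp, params = qc_params(), species = NULL) {
  stopifnot(inherits(exp, "pdx_experiment"))
  umis <- as.numeric(Matrix::colSums(exp$counts))
  n_genes <- as.numeric(Matrix::colSums(exp$counts >= 1))
  mito <- stringr::str_detect(exp$genes$gene_name, params$mito_pattern)
  mito_frac <- as.numeric(Matrix::colSums(exp$counts[mito, , drop = FALSE])) /
    pmax(umis, 1)
  # per-cell normalized housekeeping mean; depends only on the cell itself.
  # Cells labeled mouse are checked against the mouse housekeeping symbols.
  hk_mean_for <- function(hk_genes, cols) {
    hk_idx <- match(hk_genes, exp$genes$gene_name)
    if (anyNA(hk_idx)) {
      abort(paste0("housekeeping gene(s) absent from features: ",
                   paste(hk_genes[is.na(hk_idx)], collapse = ", ")))
    }
    hk_counts <- as.matrix(exp$counts[hk_idx, cols, drop = FALSE])
    colMeans(log2(1 + 1e6 * sweep(hk_counts, 2, pmax(umis[cols], 1), "/")))
  }
  is_mouse <- rep(FALSE, ncol(exp$counts))
  if (!is.null(species)) {
    is_mouse <- exp$cells$barcode %in%
      species$barcode[species$species == "mouse"]
  }
  hk_mean <- numeric(ncol(exp$counts))
  if (any(!is_mouse)) {
    hk_mean[!is_mouse] <- hk_mean_for(params$housekeeping_genes, which(!is_mouse))
  }
  if (any(is_mouse)) {
    hk_mean[is_mouse] <- hk_mean_for(params$housekeeping_genes_mouse,
                                     which(is_mouse))
  }

  report <- tibble(
    barcode = exp$cells$barcode, umis = umis, n_genes = n_genes,
    mito_fraction = mito_frac, housekeeping_mean = hk_mean
  )
  is_multiplet <- if (is.null(species)) rep(FALSE, nrow(report)) else {
    report$barcode %in% species$barcode[species$species == "multiplet"]
  }
  fail_umi <- umis < params$umi_min | umis > params$umi_max
  fail_genes <- n_genes < params$genes_min | n_genes > params$genes_max
  fail_mito <- mito_frac > params$mito_fraction_max
  fail_hk <- hk_mean < params$housekeeping_min_mean
  rule <- dplyr::case_when(
    is_multiplet ~ "multiplet",
    fail_umi ~ ifelse(umis < params$umi_min, "umi_min", "umi_max"),
    fail_genes ~ ifelse(n_genes < params$genes_min, "genes_min", "genes_max"),
    fail_mito ~ "mito",
    fail_hk ~ "housekeeping",
    TRUE ~ NA_character_
  )
  report <- mutate(report, retained = is.na(rule), rule = rule)
  class(report) <- c("scpdx_qc_report", class(report))
  list(experiment = keep_cells(exp, report$barcode[report$retained]),
       report = report)
}

#' @method glance scpdx_qc_report
#' @export
glance.scpdx_qc_report <- function(x, ...) {
  removed <- table(factor(x$rule, levels = c("multiplet", "umi_min", "umi_max",
                                             "genes_min", "genes_max", "mito",
                                             "housekeeping")))
  bind_cols(tibble(n_input = nrow(x), n_retained = sum(x$retained)),
            as_tibble(t(as.matrix(removed))))
}

#' Strict expressed-gene filter for tumor clusters
#'
#' Tumor cells carry more expressed genes than stromal/immune cells, so
#' cluster-level malignant calls are held to a stricter floor: tumor
#' barcodes must exceed `tumor_cluster_genes_min` expressed genes (strict
#' \code{>}); non-tumor barcodes are untouched.
#'
#' @inheritParams assign_species
#' @param tumor_barcodes barcodes of cells in tumor clusters
#' @return character vector of retained barcodes (whole matrix)
#' @export
strict_tumor_filter <- function(exp, tumor_barcodes, params = qc_params()) {
  stopifnot(all(tumor_barcodes %in% exp$cells$barcode))
  n_genes <- setNames(as.numeric(Matrix::colSums(exp$counts >= 1)),
                      exp$cells$barcode)
  drop <- tumor_barcodes[n_genes[tumor_barcodes] <= params$tumor_cluster_genes_min]
  setdiff(exp$cells$barcode, drop)
}

#' Optional cluster-purity filter
#'
#' Flags cells whose cluster label disagrees with the majority label among
#' their k nearest neighbours in PC space; an explicit, logged stand-in for
#' ad-hoc per-cluster outlier removal.
#'
#' @param pc_scores matrix of cells x PCs, rownames = barcodes
#' @param clusters tibble (barcode, cluster)
#' @param k neighbourhood size
#' @return tibble (barcode, cluster, neighbourhood_cluster, outlier)
#' @export
cluster_purity_filter <- function(pc_scores, clusters, k = 20) {
  stopifnot(nrow(pc_scores) == nrow(clusters))
  idx <- match(clusters$barcode, rownames(pc_scores))
  stopifnot(!anyNA(idx))
  pc_scores <- pc_scores[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(pc_scores))
  diag(d) <- Inf
  lab <- clusters$cluster
  nb <- apply(d, 1, function(row) {
    nn <- order(row)[seq_len(min(k, length(row) - 1))]
    names(which.max(table(lab[nn])))
  })
  out <- tibble(barcode = clusters$barcode, cluster = lab,
                neighbourhood_cluster = nb,
                outlier = lab != nb)
  if (any(out$outlier)) {
    inform(sprintf("cluster purity filter flags %d/%d cells", sum(out$outlier),
                   nrow(out)))
  }
  out
}
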