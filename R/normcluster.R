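#' Drop genes expressed in fewer than a fraction of cells
#'
#' Retains genes with a nonzero count in at least `min_fraction` of cells
#' (inclusive), removing low-expression genes while keeping genes private to
#' rare cell types.
#'
#' @param exp a [pdx_experiment()]
#' @param min_fraction minimum expressing-cell fraction (default 1%)
#' @return the filtered `pdx_experiment`
#' @export
gene_prevalence_filter <- function(exp, min_fraction = 0.01) {
  stopifnot(inherits(exp, "pdx_experiment"))
  n <- ncol(exp$counts)
  if (n < 100) {
    warn(sprintf("only %d cells; a %.0f%% prevalence threshold is degenerate",
                 n, 100 * min_fraction))
  }
  n_expressing <- Matrix::rowSums(exp$counts >= 1)
  keep_genes(exp, exp$genes$gene_id[n_expressing >= min_fraction * n])
}

#' TPM-like normalization
#'
#' Depth-normalizes each cell to a fixed total (default 1e6; no gene-length
#' correction, as appropriate for 3' UMI data) and log2-transforms after
#' adding one: value = log2(1 + scale_factor * count / cell_total). The
#' normalized matrix is stored sparse on `exp$norm`.
#'
#' @inheritParams gene_prevalence_filter
#' @param scale_factor per-cell total after normalization
#' @return the `pdx_experiment` with `$norm` set
#' @export
normalize_tpm <- function(exp, scale_factor = 1e6) {
  stopifnot(inherits(exp, "pdx_experiment"))
  depth <- Matrix::colSums(exp$counts)
  if (any(depth == 0)) {
    abort("zero-depth cell encountered; run QC before normalization")
  }
  norm <- exp$counts
  # dgCMatrix: scale the nonzero entries column-wise, zeros map to log2(1)=0
  col_of <- rep(seq_len(ncol(norm)), diff(norm@p))
  norm@x <- log2(1 + scale_factor * norm@x / depth[col_of])
  exp$norm <- norm
  exp
}

norm_matrix <- function(exp) {
  if (is.null(exp$norm)) abort("experiment is not normalized; call normalize_tpm()")
  exp$norm
}

#' Select variable genes by binned dispersion
#'
#' Genes are binned by mean normalized expression (equal-frequency bins);
#' within each bin the dispersion (variance/mean) is z-scored, and genes
#' whose z-scored dispersion exceeds the cutoff are selected. Constant genes
#' are never selected.
#'
#' @inheritParams gene_prevalence_filter
#' @param n_bins number of mean-expression bins
#' @param dispersion_cutoff z-scored dispersion threshold
#' @return character vector of selected gene ids
#' @export
select_variable_genes <- function(exp, n_bins = 20, dispersion_cutoff = 1) {
  m <- norm_matrix(exp)
  if (ncol(m) < 2) abort("need at least 2 cells")
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- (ex2 - mu^2) * ncol(m) / (ncol(m) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bin <- dplyr::ntile(mu, n_bins)
  z <- stats::ave(disp, bin, FUN = function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  sel <- z > dispersion_cutoff & v > 0
  exp$genes$gene_id[sel]
}

#' PCA and graph-based clustering
#'
#' Per-gene z-scores (capped at `scale_cap`) of the variable genes feed a
#' PCA; a k-nearest-neighbour graph on the leading `n_pcs` components is
#' clustered by Louvain modularity optimisation at the given resolution.
#' Deterministic for a fixed seed.
#'
#' @inheritParams gene_prevalence_filter
#' @param variable_genes gene ids to use (default: [select_variable_genes()])
#' @param n_pcs number of principal components (default 20)
#' @param resolution Louvain resolution
#' @param k neighbours in the kNN graph
#' @param scale_cap cap on per-gene z-scores before PCA
#' @param seed RNG seed for the community search
#' @return a `scpdx_clusters` object: `clusters` tibble (barcode, cluster),
#'   `pc_scores` (cells x PCs), `variable_genes`, `sdev`
#' @export
reduce_and_cluster <- function(exp, variable_genes = NULL, n_pcs = 20,
                               resolution = 1, k = 20, scale_cap = 10,
                               seed = 1L) {
  m <- norm_matrix(exp)
  if (is.null(variable_genes)) variable_genes <- select_variable_genes(exp)
  if (length(variable_genes) < n_pcs) {
    abort(sprintf("%d variable genes < n_pcs = %d", length(variable_genes), n_pcs))
  }
  if (ncol(m) <= n_pcs) {
    abort(sprintf("%d cells <= n_pcs = %d; reduce n_pcs", ncol(m), n_pcs))
  }
  x <- t(as.matrix(m[match(variable_genes, exp$genes$gene_id), , drop = FALSE]))
  x <- scale(x)
  x[is.na(x)] <- 0
  x[x > scale_cap] <- scale_cap
  x[x < -scale_cap] <- -scale_cap
  pca <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pca$x
  rownames(scores) <- exp$cells$barcode
  k_eff <- min(k, nrow(scores) - 1)
  d <- as.matrix(stats::dist(scores))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_eff)]))
  edges <- cbind(rep(seq_len(nrow(nn)), each = k_eff), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  clusters <- tibble(
    barcode = exp$cells$barcode,
    cluster = paste0("C", igraph::membership(comm))
  )
  structure(
    list(clusters = clusters, pc_scores = scores,
         variable_genes = variable_genes, sdev = pca$sdev),
    class = "scpdx_clusters"
  )
}

#' @method print scpdx_clusters
#' @export
print.scpdx_clusters <- function(x, ...) {
  cat(sprintf("<scpdx_clusters> %d cells in %d clusters\n",
              nrow(x$clusters), dplyr::n_distinct(x$clusters$cluster)))
  print(count(x$clusters, .data$cluster))
  invisible(x)
}

#' @method tidy scpdx_clusters
#' @export
tidy.scpdx_clusters <- function(x, ...) x$clusters

#' @method glance scpdx_clusters
#' @export
glance.scpdx_clusters <- function(x, ...) {
  tibble(n_cells = nrow(x$clusters),
         n_clusters = dplyr::n_distinct(x$clusters$cluster),
         n_variable_genes = length(x$variable_genes),
         n_pcs = ncol(x$pc_scores))
}

#' Annotate clusters with marker-gene programs
#'
#' Each cluster is labeled with the cell type whose marker set has the
#' highest cluster-mean of the per-cell mean marker expression; ties break
#' alphabetically with a warning. Marker genes are matched by gene name;
#' missing genes are dropped with a warning.
#'
#' @inheritParams gene_prevalence_filter
#' @param clusters a `scpdx_clusters` object or tibble (barcode, cluster)
#' @param marker_map named list cell-type -> marker gene names
#' @return tibble (cluster, cell_type, score), with the full score matrix in
#'   attribute `"scores"`
#' @export
annotate_clusters <- function(exp, clusters, marker_map) {
  m <- norm_matrix(exp)
  if (inherits(clusters, "scpdx_clusters")) clusters <- clusters$clusters
  stopifnot(all(clusters$barcode %in% exp$cells$barcode))
  present <- lapply(marker_map, intersect, y = exp$genes$gene_name)
  dropped <- sum(lengths(marker_map)) - sum(lengths(present))
  if (dropped > 0) warn(sprintf("%d marker gene(s) absent from the matrix", dropped))
  if (all(lengths(present) == 0)) abort("no marker gene present for any cell type")
  cell_idx <- match(clusters$barcode, exp$cells$barcode)
  per_type <- vapply(present, function(gs) {
    if (!length(gs)) return(rep(NA_real_, nrow(clusters)))
    rows <- match(gs, exp$genes$gene_name)
    colMeans(as.matrix(m[rows, cell_idx, drop = FALSE]))
  }, numeric(nrow(clusters)))
  score_tbl <- bind_cols(clusters["cluster"], as_tibble(per_type)) %>%
    group_by(.data$cluster) %>%
    summarise(across(dplyr::everything(), mean), .groups = "drop")
  scores <- as.matrix(score_tbl[, -1])
  rownames(scores) <- score_tbl$cluster
  assign_one <- function(row) {
    ok <- which(!is.na(row))
    best <- ok[row[ok] == max(row[ok])]
    if (length(best) > 1) {
      warn(paste0("tied marker scores; alphabetical tie-break among ",
                  paste(names(row)[best], collapse = ", ")))
      best <- best[order(names(row)[best])][1]
    }
    best
  }
  idx <- apply(scores, 1, assign_one)
  out <- tibble(cluster = rownames(scores),
                cell_type = colnames(scores)[idx],
                score = scores[cbind(seq_len(nrow(scores)), idx)])
  attr(out, "scores") <- scores
  out
}

#' Differential expression by per-gene t test
#'
#' Welch two-sample t tests on log-normalized expression, after the usual
#' Seurat-style pre-filter: a gene must be expressed in at least
#' `min_fraction` of either group and have |log2 fold-change| >=
#' `min_logfc`. P-values are Bonferroni-adjusted over the tested genes. The
#' `highlight` flag marks |logFC| > 0.8 with p < 0.001.
#'
#' @inheritParams gene_prevalence_filter
#' @param cells_a,cells_b disjoint barcode sets (each >= 2 cells)
#' @param min_fraction expression-fraction pre-filter
#' @param min_logfc absolute log2 fold-change pre-filter
#' @param highlight_logfc,highlight_p thresholds for the reporting flag
#' @return tibble (gene_id, gene_name, logfc, statistic, p.value, p.adjusted,
#'   highlight), sorted by p
#' @export
differential_expression <- function(exp, cells_a, cells_b,
                                    min_fraction = 0.1, min_logfc = 0.25,
                                    highlight_logfc = 0.8,
                                    highlight_p = 1e-3) {
  m <- norm_matrix(exp)
  ia <- match(cells_a, exp$cells$barcode)
  ib <- match(cells_b, exp$cells$barcode)
  if (anyNA(ia) || anyNA(ib)) abort("unknown barcodes in group membership")
  if (length(intersect(cells_a, cells_b))) abort("groups must be disjoint")
  if (length(ia) < 2 || length(ib) < 2) abort("each group needs >= 2 cells")
  a <- as.matrix(m[, ia, drop = FALSE])
  b <- as.matrix(m[, ib, drop = FALSE])
  na <- ncol(a); nb <- ncol(b)
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  va <- rowSums((a - mu_a)^2) / (na - 1)
  vb <- rowSums((b - mu_b)^2) / (nb - 1)
  logfc <- mu_a - mu_b
  frac_a <- rowMeans(a > 0); frac_b <- rowMeans(b > 0)
  keep <- (pmax(frac_a, frac_b) >= min_fraction) & (abs(logfc) >= min_logfc)
  se2 <- va / na + vb / nb
  stat <- ifelse(se2 > 0, logfc / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)), 1)
  p <- ifelse(se2 > 0, 2 * pt(abs(stat), df, lower.tail = FALSE), 1)
  out <- tibble(
    gene_id = exp$genes$gene_id, gene_name = exp$genes$gene_name,
    logfc = unname(logfc), statistic = unname(stat), p.value = unname(p)
  )[keep, ]
  out$p.adjusted <- p.adjust(out$p.value, method = "bonferroni")
  out$highlight <- abs(out$logfc) > highlight_logfc & out$p.value < highlight_p
  arrange(out, .data$p.value)
}
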