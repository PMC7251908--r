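#' Assemble a PDX droplet experiment
#'
#' The container passed between pipeline stages. Counts are kept as a sparse
#' genes x cells matrix (the orientation CellRanger writes); per-gene and
#' per-cell annotations are tibbles that accumulate columns as stages run.
#'
#' @param counts sparse (or dense) numeric matrix, genes in rows, cells in
#'   columns. Dimnames are taken from `genes$gene_id` / `cells$barcode` when
#'   absent.
#' @param genes tibble with at least `gene_id`, `gene_name`, `genome`
#'   (e.g. `"GRCh38"` or `"mm10"`); optionally `chromosome`, `start`.
#' @param cells tibble with at least `barcode`.
#'
#' @return A `pdx_experiment` object.
#' @export
pdx_experiment <- function(counts, genes, cells) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  genes <- as_tibble(genes)
  cells <- as_tibble(cells)
  stopifnot(nrow(counts) == nrow(genes), ncol(counts) == nrow(cells))
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene_id in `genes`")
  if (anyDuplicated(cells$barcode)) abort("duplicate barcode in `cells`")
  dimnames(counts) <- list(genes$gene_id, cells$barcode)
  structure(
    list(counts = counts, genes = genes, cells = cells, norm = NULL),
    class = "pdx_experiment"
  )
}

#' @method print pdx_experiment
#' @export
print.pdx_experiment <- function(x, ...) {
  cat(sprintf(
    "<pdx_experiment> %d genes x %d cells (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(unique(x$genes$genome), collapse = " + ")
  ))
  if (!is.null(x$norm)) cat("  normalized: log2(TPM-like + 1)\n")
  extra <- setdiff(names(x$cells), "barcode")
  if (length(extra)) cat("  cell annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @method dim pdx_experiment
#' @export
dim.pdx_experiment <- function(x) dim(x$counts)

#' Subset an experiment to a set of barcodes
#'
#' @param exp a [pdx_experiment()]
#' @param barcodes character vector of barcodes to keep (order preserved)
#' @return the subset `pdx_experiment`
#' @export
keep_cells <- function(exp, barcodes) {
  stopifnot(inherits(exp, "pdx_experiment"))
  missing <- setdiff(barcodes, exp$cells$barcode)
  if (length(missing)) {
    abort(paste0("unknown barcodes: ", paste(head(missing, 5), collapse = ", ")))
  }
  idx <- match(barcodes, exp$cells$barcode)
  exp$counts <- exp$counts[, idx, drop = FALSE]
  exp$cells <- exp$cells[idx, , drop = FALSE]
  if (!is.null(exp$norm)) exp$norm <- exp$norm[, idx, drop = FALSE]
  exp
}

#' Subset an experiment to a set of genes
#'
#' @inheritParams keep_cells
#' @param gene_ids character vector of gene ids to keep
#' @return the subset `pdx_experiment`
#' @export
keep_genes <- function(exp, gene_ids) {
  stopifnot(inherits(exp, "pdx_experiment"))
  idx <- match(gene_ids, exp$genes$gene_id)
  if (anyNA(idx)) abort("unknown gene ids in `gene_ids`")
  exp$counts <- exp$counts[idx, , drop = FALSE]
  exp$genes <- exp$genes[idx, , drop = FALSE]
  if (!is.null(exp$norm)) exp$norm <- exp$norm[idx, , drop = FALSE]
  exp
}

#' Attach or replace per-cell annotations
#'
#' Joins a tibble keyed by `barcode` onto the experiment's cell table.
#'
#' @inheritParams keep_cells
#' @param annotation tibble with a `barcode` column
#' @return the annotated `pdx_experiment`
#' @export
annotate_cells <- function(exp, annotation) {
  stopifnot(inherits(exp, "pdx_experiment"), "barcode" %in% names(annotation))
  keep <- c("barcode", setdiff(names(exp$cells), names(annotation)))
  exp$cells <- left_join(exp$cells[, keep, drop = FALSE], as_tibble(annotation),
                         by = "barcode")
  exp
}
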