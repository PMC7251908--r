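#' Write a simulated experiment as a CellRanger-style fixture
#'
#' Emits `matrix.mtx` (MatrixMarket coordinate, genes x cells, 1-based),
#' `barcodes.tsv`, `features.tsv` (gene_id, gene_name, genome), a
#' `gene_positions.tsv` (gene_id, chromosome, start) for positioned genes,
#' and, when ground truth is supplied, `truth.csv`.
#'
#' @param exp a [pdx_experiment()]
#' @param dir output directory (created if missing)
#' @param truth optional ground-truth tibble keyed by barcode
#' @return `dir`, invisibly
#' @export
write_fixture <- function(exp, dir, truth = NULL) {
  stopifnot(inherits(exp, "pdx_experiment"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) abort(paste0("cannot create fixture directory: ", dir))
  wrap <- function(path, fn) {
    tryCatch(fn(path), error = function(e) {
      abort(paste0("failed writing ", path, ": ", conditionMessage(e)))
    })
  }
  wrap(file.path(dir, "matrix.mtx"), function(p) Matrix::writeMM(exp$counts, p))
  wrap(file.path(dir, "barcodes.tsv"), function(p) {
    readr::write_tsv(tibble(barcode = exp$cells$barcode), p, col_names = FALSE)
  })
  wrap(file.path(dir, "features.tsv"), function(p) {
    readr::write_tsv(exp$genes[, c("gene_id", "gene_name", "genome")], p,
                     col_names = FALSE)
  })
  pos <- if (all(c("chromosome", "start") %in% names(exp$genes))) {
    exp$genes[!is.na(exp$genes$chromosome),
              c("gene_id", "chromosome", "start")]
  } else {
    tibble(gene_id = character(), chromosome = character(), start = integer())
  }
  wrap(file.path(dir, "gene_positions.tsv"), function(p) readr::write_tsv(pos, p))
  if (!is.null(truth)) {
    wrap(file.path(dir, "truth.csv"), function(p) readr::write_csv(truth, p))
  }
  invisible(dir)
}

#' Read a CellRanger-style matrix directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (2 or 3 columns;
#' the third is the genome tag). A `gene_positions.tsv`, when present, is
#' joined onto the gene table.
#'
#' @param dir directory containing the matrix trio
#' @return a [pdx_experiment()]
#' @export
read_pdx_matrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) abort(paste0("missing input file(s): ",
                                    paste(missing, collapse = ", ")))
  m <- Matrix::readMM(paths[1])
  barcodes <- readr::read_tsv(paths[2], col_names = "barcode",
                              col_types = "c", progress = FALSE)
  features <- readr::read_tsv(paths[3], col_names = FALSE,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  names(features) <- c("gene_id", "gene_name", "genome")[seq_len(ncol(features))]
  if (!"genome" %in% names(features)) features$genome <- NA_character_
  pos_path <- file.path(dir, "gene_positions.tsv")
  if (file.exists(pos_path)) {
    pos <- read_gene_positions(pos_path)
    features <- left_join(features, pos, by = "gene_id")
  }
  pdx_experiment(m, features, barcodes)
}

#' Read a gene-position table
#'
#' @param path TSV with columns gene_id (or gene), chromosome, start
#' @return tibble (gene_id, chromosome, start)
#' @export
read_gene_positions <- function(path) {
  pos <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if ("gene" %in% names(pos) && !"gene_id" %in% names(pos)) {
    pos <- rename(pos, gene_id = "gene")
  }
  need <- c("gene_id", "chromosome", "start")
  if (!all(need %in% names(pos))) {
    abort(paste0(path, " must have columns gene_id, chromosome, start"))
  }
  mutate(pos[, need], chromosome = as.character(.data$chromosome),
         start = as.integer(.data$start))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: set name, description, then gene symbols, tab-separated
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
  if (anyDuplicated(names(sets))) abort("duplicate gene-set names in GMT")
  if (any(lengths(sets) == 0)) abort("empty gene set in GMT")
  sets
}

#' Read a ligand-receptor pair table
#'
#' @param path TSV with columns ligand, receptor and optionally a class/
#'   annotation column
#' @return tibble with unique (ligand, receptor) rows
#' @export
read_lr_pairs <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab))) {
    abort("pair table needs columns ligand, receptor")
  }
  if (any(!nzchar(tab$ligand) | !nzchar(tab$receptor))) abort("empty gene name in pair table")
  distinct(tab, .data$ligand, .data$receptor, .keep_all = TRUE)
}

#' Validate a matrix directory before running the pipeline
#'
#' Checks MTX/TSV consistency (dimensions, duplicate barcodes, genome tags)
#' and gene-position coverage. Dimension mismatches are fatal; everything
#' else is returned as findings.
#'
#' @param dir directory with matrix.mtx, barcodes.tsv, features.tsv
#' @return tibble of findings (level, message); zero rows when clean
#' @export
validate_inputs <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) abort(paste0("missing input file(s): ",
                                    paste(missing, collapse = ", ")))
  m <- Matrix::readMM(paths[1])
  barcodes <- readr::read_tsv(paths[2], col_names = "barcode",
                              col_types = "c", progress = FALSE)
  features <- readr::read_tsv(paths[3], col_names = FALSE,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  if (nrow(features) != nrow(m)) {
    abort(sprintf("features rows (%d) do not match matrix rows (%d)",
                  nrow(features), nrow(m)))
  }
  if (nrow(barcodes) != ncol(m)) {
    abort(sprintf("barcode rows (%d) do not match matrix columns (%d)",
                  nrow(barcodes), ncol(m)))
  }
  findings <- tibble(level = character(), message = character())
  add <- function(level, msg) {
    findings <<- bind_rows(findings, tibble(level = level, message = msg))
  }
  dup <- barcodes$barcode[duplicated(barcodes$barcode)]
  for (d in unique(dup)) add("warning", paste0("duplicate barcode: ", d))
  if (ncol(features) < 3) {
    add("warning", "features.tsv has no genome tag column")
  } else if (length(unique(features[[3]])) < 2) {
    add("info", paste0("single genome tag: ", unique(features[[3]])[1]))
  }
  pos_path <- file.path(dir, "gene_positions.tsv")
  if (file.exists(pos_path)) {
    pos <- read_gene_positions(pos_path)
    n_cov <- sum(features[[1]] %in% pos$gene_id)
    if (n_cov == 0) add("warning", "gene_positions.tsv covers no feature")
  } else {
    add("info", "no gene_positions.tsv; CNV inference will need one")
  }
  for (f in findings$message[findings$level == "warning"]) warn(f)
  findings
}
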