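#' Pipeline configuration
#'
#' Collects the input directory, output directory, per-stage parameter
#' blocks, stage toggles, and the single global seed from which every
#' stochastic stage derives its sub-stream.
#'
#' @param input_dir directory with matrix.mtx / barcodes.tsv / features.tsv
#'   (and gene_positions.tsv for the CNV stage)
#' @param out_dir run directory for outputs
#' @param qc a [qc_params()]
#' @param cnv a [cnv_params()]
#' @param clustering list: n_pcs, resolution, k, n_bins, dispersion_cutoff
#' @param marker_genes named list cell-type -> markers for annotation
#' @param tumor_cell_types annotated types regarded as malignant candidates;
#'   human cells of other types anchor the CNV baseline
#' @param cycle_genes list with g1s / g2m panels
#' @param lr_pairs tibble (ligand, receptor) or path to a pair TSV;
#'   default: the bundled immune-checkpoint table
#' @param stages named logical vector toggling qc, cluster, cnv, signatures,
#'   lr
#' @param seed global integer seed
#' @return a `scpdx_pipeline_config` list
#' @export
pipeline_config <- function(input_dir, out_dir,
                            qc = qc_params(), cnv = cnv_params(),
                            clustering = list(n_pcs = 20, resolution = 1,
                                              k = 20, n_bins = 20,
                                              dispersion_cutoff = 1),
                            marker_genes = default_marker_genes(),
                            tumor_cell_types = "tumor",
                            cycle_genes = default_cycle_genes(),
                            lr_pairs = NULL,
                            stages = c(qc = TRUE, cluster = TRUE, cnv = TRUE,
                                       signatures = TRUE, lr = TRUE),
                            seed = 1L) {
  if (is.character(lr_pairs)) lr_pairs <- read_lr_pairs(lr_pairs)
  if (is.null(lr_pairs)) {
    lr_pairs <- read_lr_pairs(system.file("extdata", "checkpoint_lr_pairs.tsv",
                                          package = "scpdx"))
  }
  structure(
    list(input_dir = input_dir, out_dir = out_dir, qc = qc, cnv = cnv,
         clustering = clustering, marker_genes = marker_genes,
         tumor_cell_types = tumor_cell_types,
         cycle_genes = cycle_genes, lr_pairs = lr_pairs,
         stages = stages, seed = as.integer(seed)),
    class = "scpdx_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: input_dir, out_dir, seed, stages, qc, cnv, clustering,
#' lr_pairs (a path); unknown keys under qc/cnv/clustering are rejected by
#' the corresponding constructors.
#'
#' @param path YAML file
#' @return a `scpdx_pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$input_dir) || is.null(y$out_dir)) {
    abort("pipeline YAML needs input_dir and out_dir")
  }
  args <- list(input_dir = y$input_dir, out_dir = y$out_dir)
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$qc)) args$qc <- do.call(qc_params, y$qc)
  if (!is.null(y$cnv)) args$cnv <- do.call(cnv_params, y$cnv)
  if (!is.null(y$clustering)) {
    args$clustering <- modifyList(formals(pipeline_config)$clustering |>
                                    eval(), y$clustering)
  }
  if (!is.null(y$lr_pairs)) args$lr_pairs <- y$lr_pairs
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  do.call(pipeline_config, args)
}

#' Run the pipeline end-to-end
#'
#' Fixed stage order: validate + load, species demultiplexing, QC filters,
#' normalization + clustering + annotation, CNV inference and malignancy
#' calling (human cells), cell-cycle signatures (human tumor cells),
#' ligand-receptor network. Each stage writes its table under `out_dir`;
#' `manifest.json` records parameters, seed, input hashes and per-stage cell
#' counts. A failing stage aborts with its name; earlier outputs are kept.
#'
#' @param config a [pipeline_config()] or path to a YAML file
#' @return the manifest list, invisibly; outputs are written to
#'   `config$out_dir`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "scpdx_pipeline_config"))
  out <- config$out_dir
  ok <- dir.exists(out) || dir.create(out, recursive = TRUE)
  if (!ok) abort(paste0("cannot create run directory: ", out))
  enabled <- function(s) isTRUE(config$stages[[s]])
  manifest <- list(
    seed = config$seed,
    parameters = list(qc = unclass(config$qc), cnv = unclass(config$cnv),
                      clustering = config$clustering),
    input_hashes = as.list(tools::md5sum(list.files(config$input_dir,
                                                    full.names = TRUE))),
    stages = list()
  )
  note <- function(stage, status, n_cells = NA) {
    manifest$stages[[stage]] <<- list(status = status, n_cells = n_cells)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      note(stage, "failed")
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      abort(paste0("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)))
    })
  }

  exp <- run_stage("validate", function() {
    validate_inputs(config$input_dir)
    read_pdx_matrix(config$input_dir)
  })
  note("validate", "completed", ncol(exp$counts))

  species <- run_stage("species", function() {
    sp <- assign_species(exp, config$qc)
    readr::write_csv(sp, file.path(out, "species.csv"))
    sp
  })
  note("species", "completed", sum(species$species != "multiplet"))

  if (enabled("qc")) {
    qc_res <- run_stage("qc", function() {
      res <- filter_cells(exp, config$qc, species = species)
      readr::write_csv(res$report, file.path(out, "qc_report.csv"))
      res
    })
    exp <- qc_res$experiment
    note("qc", "completed", ncol(exp$counts))
  } else note("qc", "skipped")

  exp <- run_stage("normalize", function() {
    normalize_tpm(gene_prevalence_filter(exp))
  })
  note("normalize", "completed", ncol(exp$counts))
  exp <- annotate_cells(exp, select(species, "barcode", "species"))

  clusters <- NULL
  if (enabled("cluster")) {
    clusters <- run_stage("cluster", function() {
      cl <- reduce_and_cluster(exp, n_pcs = config$clustering$n_pcs,
                               resolution = config$clustering$resolution,
                               k = config$clustering$k,
                               seed = sub_seed(config$seed, 11L))
      ann <- annotate_clusters(exp, cl, config$marker_genes)
      labelled <- left_join(cl$clusters, ann[, c("cluster", "cell_type")],
                            by = "cluster")
      readr::write_csv(labelled, file.path(out, "clusters.csv"))
      list(clusters = cl, labels = labelled)
    })
    exp <- annotate_cells(exp, clusters$labels)
    note("cluster", "completed", nrow(clusters$labels))
  } else note("cluster", "skipped")

  cnv <- NULL
  if (enabled("cnv")) {
    cnv <- run_stage("cnv", function() {
      human <- species$barcode[species$species == "human"]
      human <- intersect(human, exp$cells$barcode)
      hexp <- keep_cells(exp, human)
      hexp <- keep_genes(hexp, hexp$genes$gene_id[hexp$genes$genome %in%
                                                    c("GRCh38", "hg38", "hg19", "human")])
      baseline <- NULL
      if ("cell_type" %in% names(hexp$cells)) {
        baseline <- hexp$cells$barcode[
          !is.na(hexp$cells$cell_type) &
            !hexp$cells$cell_type %in% config$tumor_cell_types]
        if (length(baseline) < 2) baseline <- NULL
      }
      res <- infer_cnv(hexp, params = config$cnv, baseline_cells = baseline)
      readr::write_csv(res$calls, file.path(out, "cnv_calls.csv"))
      readr::write_csv(
        bind_cols(tibble(gene_id = res$genes$gene_id),
                  as_tibble(as.data.frame(res$matrix))),
        file.path(out, "cnv_matrix.csv"))
      res
    })
    exp <- annotate_cells(exp, select(cnv$calls, "barcode", cnv_call = "call"))
    note("cnv", "completed", nrow(cnv$calls))
  } else note("cnv", "skipped")

  if (enabled("signatures")) {
    cyc <- run_stage("signatures", function() {
      target <- if (!is.null(cnv)) {
        cnv$calls$barcode[cnv$calls$call == "tumor"]
      } else exp$cells$barcode
      if (length(target) < 2) target <- exp$cells$barcode
      sc <- cycle_scores(keep_cells(exp, target), config$cycle_genes)
      readr::write_csv(sc, file.path(out, "cycle.csv"))
      sc
    })
    note("signatures", "completed", nrow(cyc))
  } else note("signatures", "skipped")

  if (enabled("lr")) {
    net <- run_stage("lr", function() {
      if (!"cell_type" %in% names(exp$cells) ||
          all(is.na(exp$cells$cell_type))) {
        abort("ligand-receptor stage needs cell-type annotations")
      }
      net <- count_pairs(exp, config$lr_pairs)
      export_network(net, out)
      net
    })
    note("lr", "completed", sum(!is.na(exp$cells$cell_type)))
  } else note("lr", "skipped")

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
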