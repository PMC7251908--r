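resolve_cell_types <- function(exp, cell_types) {
  if (is.null(cell_types)) {
    if (!"cell_type" %in% names(exp$cells)) {
      abort("no cell types: annotate cells or pass `cell_types`")
    }
    return(exp$cells[, c("barcode", "cell_type")])
  }
  ct <- as_tibble(cell_types)
  stopifnot(all(c("barcode", "cell_type") %in% names(ct)))
  ct[match(exp$cells$barcode, ct$barcode), c("barcode", "cell_type")]
}

#' Fraction of cells per type expressing a gene
#'
#' @param exp a normalized [pdx_experiment()]
#' @param genes gene names to evaluate
#' @param cell_types tibble (barcode, cell_type); defaults to the
#'   experiment's `cell_type` annotation
#' @param threshold expression above which a cell counts as expressing
#' @return tibble (cell_type, gene, n_cells, n_expressing, fraction)
#' @export
expressing_fraction <- function(exp, genes, cell_types = NULL, threshold = 0) {
  m <- norm_matrix(exp)
  ct <- resolve_cell_types(exp, cell_types)
  idx <- match(genes, exp$genes$gene_name)
  if (anyNA(idx)) {
    abort(paste0("unknown gene(s): ", paste(genes[is.na(idx)], collapse = ", ")))
  }
  expr <- as.matrix(m[idx, , drop = FALSE] > threshold)
  rownames(expr) <- genes
  purrr::map_dfr(genes, function(g) {
    tibble(cell_type = ct$cell_type, expressing = expr[g, ]) %>%
      group_by(.data$cell_type) %>%
      summarise(gene = g, n_cells = n(), n_expressing = sum(.data$expressing),
                fraction = mean(.data$expressing), .groups = "drop")
  }) %>%
    select("cell_type", "gene", "n_cells", "n_expressing", "fraction")
}

#' Count ligand-receptor cell pairs between cell types
#'
#' For each (ligand, receptor) pair and each ordered (sender, receiver)
#' type pair — self-pairs included — the interaction count is the number of
#' sender cells expressing the ligand times the number of receiver cells
#' expressing the receptor (every expressing cell pairs with every
#' expressing cell). Zero-count combinations yield no edge. Edge weights
#' are the fixed drawing rescalings count/4e6; node sizes are cell
#' count/20. The `draw` flag marks edges whose sender ligand-expressing
#' fraction exceeds `draw_fraction` (a reporting filter only; counts are
#' unmodified).
#'
#' @inheritParams expressing_fraction
#' @param pairs tibble (ligand, receptor[, class]); see [read_lr_pairs()]
#' @param draw_fraction sender expressing-fraction threshold for the flag
#' @return a `scpdx_network`: `edges` tibble (sender, receiver, ligand,
#'   receptor, count, scaled_weight, draw), `nodes` tibble (cell_type,
#'   n_cells, size), `fractions` from [expressing_fraction()]
#' @export
count_pairs <- function(exp, pairs, cell_types = NULL, threshold = 0,
                        draw_fraction = 0.1) {
  if (ncol(exp$counts) < 2) abort("need at least 2 cells")
  ct <- resolve_cell_types(exp, cell_types)
  pairs <- as_tibble(pairs)
  nodes <- count(ct, .data$cell_type, name = "n_cells") %>%
    mutate(size = .data$n_cells / 20)
  empty_edges <- tibble(sender = character(), receiver = character(),
                        ligand = character(), receptor = character(),
                        count = numeric(), scaled_weight = numeric(),
                        draw = logical())
  if (!nrow(pairs)) {
    warn("empty ligand-receptor pair table; returning an empty network")
    return(structure(list(edges = empty_edges, nodes = nodes,
                          fractions = tibble()), class = "scpdx_network"))
  }
  genes <- unique(c(pairs$ligand, pairs$receptor))
  present <- genes[genes %in% exp$genes$gene_name]
  absent <- setdiff(genes, present)
  if (length(absent)) {
    warn(paste0("pair gene(s) absent from matrix: ",
                paste(absent, collapse = ", ")))
    pairs <- filter(pairs, .data$ligand %in% present, .data$receptor %in% present)
  }
  if (!nrow(pairs)) {
    return(structure(list(edges = empty_edges, nodes = nodes,
                          fractions = tibble()), class = "scpdx_network"))
  }
  fr <- expressing_fraction(exp, present, ct, threshold)
  edges <- purrr::pmap_dfr(pairs, function(ligand, receptor, ...) {
    fl <- filter(fr, .data$gene == ligand)
    frc <- filter(fr, .data$gene == receptor)
    tidyr::crossing(sender = fl$cell_type, receiver = frc$cell_type) %>%
      left_join(select(fl, sender = "cell_type", n_lig = "n_expressing",
                       lig_fraction = "fraction"), by = "sender") %>%
      left_join(select(frc, receiver = "cell_type", n_rec = "n_expressing"),
                by = "receiver") %>%
      mutate(ligand = ligand, receptor = receptor,
             count = .data$n_lig * .data$n_rec,
             scaled_weight = .data$count / 4e6,
             draw = .data$lig_fraction > draw_fraction) %>%
      filter(.data$count > 0) %>%
      select("sender", "receiver", "ligand", "receptor", "count",
             "scaled_weight", "draw")
  })
  structure(list(edges = edges, nodes = nodes, fractions = fr),
            class = "scpdx_network")
}

#' @method print scpdx_network
#' @export
print.scpdx_network <- function(x, ...) {
  cat(sprintf("<scpdx_network> %d edges between %d cell types\n",
              nrow(x$edges), nrow(x$nodes)))
  invisible(x)
}

#' @method tidy scpdx_network
#' @export
tidy.scpdx_network <- function(x, ...) x$edges

#' @method glance scpdx_network
#' @export
glance.scpdx_network <- function(x, ...) {
  tibble(n_edges = nrow(x$edges), n_nodes = nrow(x$nodes),
         total_pairs = sum(x$edges$count),
         n_drawn = sum(x$edges$draw))
}

#' Export an interaction network
#'
#' Writes `edges.csv` (sender, receiver, ligand, receptor, count,
#' scaled_weight, draw) and `nodes.json` (cell_type, n_cells, size).
#'
#' @param network a `scpdx_network`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
export_network <- function(network, dir) {
  stopifnot(inherits(network, "scpdx_network"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) abort(paste0("cannot create directory: ", dir))
  tryCatch({
    readr::write_csv(network$edges, file.path(dir, "edges.csv"))
    jsonlite::write_json(network$nodes, file.path(dir, "nodes.json"),
                         dataframe = "rows", digits = NA)
  }, error = function(e) {
    abort(paste0("failed writing network under ", dir, ": ",
                 conditionMessage(e)))
  })
  invisible(dir)
}

#' Read back an exported network
#'
#' @param dir directory holding `edges.csv` and `nodes.json`
#' @return a `scpdx_network`
#' @export
import_network <- function(dir) {
  edges <- readr::read_csv(file.path(dir, "edges.csv"),
                           col_types = readr::cols(), progress = FALSE)
  nodes <- as_tibble(jsonlite::read_json(file.path(dir, "nodes.json"),
                                         simplifyVector = TRUE))
  structure(list(edges = edges, nodes = nodes, fractions = tibble()),
            class = "scpdx_network")
}

#' @rdname autoplot_scpdx
#' @method autoplot scpdx_network
#' @export
autoplot.scpdx_network <- function(object, ...) {
  edges <- mutate(object$edges,
                  pair = paste0(.data$ligand, ":", .data$receptor))
  ggplot(edges, aes(x = .data$sender, y = .data$receiver,
                    size = .data$count, colour = .data$draw)) +
    geom_point(alpha = 0.8) +
    scale_size_area() +
    facet_wrap(~pair) +
    labs(x = "sender (ligand)", y = "receiver (receptor)",
         colour = "ligand > 10% of senders") +
    theme_bw()
}
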