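#' Default marker programs for the simulated cell types
#'
#' Canonical epithelial/basal, fibroblast, macrophage and T-cell markers;
#' human symbols for human types, mouse-cased symbols for mouse types.
#' @return named list cell-type -> marker gene names
#' @export
default_marker_genes <- function() {
  list(
    tumor = c("EPCAM", "KRT5", "KRT6A", "KRT14", "KRT17",
              "CDH1", "CLDN4", "S100A2", "SFN", "DSP"),
    stromal = c("COL1A1", "COL1A2", "COL3A1", "DCN", "LUM",
                "PDGFRA", "ACTA2", "TAGLN", "FN1", "POSTN"),
    fibroblast = c("Col1a1", "Col1a2", "Col3a1", "Dcn", "Lum",
                   "Pdgfra", "Acta2", "Tagln", "Fn1", "Postn"),
    macrophage = c("Cd68", "Lyz2", "Csf1r", "Adgre1", "Itgam",
                   "Mrc1", "Arg1", "Apoe", "Ccl2", "Cxcl1"),
    tcell = c("Cd3e", "Cd3d", "Cd8a", "Cd4", "Lck",
              "Ccl5", "Gzmb", "Nkg7", "Il7r", "Trbc1")
  )
}

#' Cell-cycle phase programs used by the simulator
#'
#' Standard G1/S (replication) and G2/M (mitosis) gene panels.
#' @return named list with elements `g1s` and `g2m`
#' @export
default_cycle_genes <- function() {
  list(
    g1s = c("MCM5", "PCNA", "TYMS", "FEN1", "MCM2", "MCM4", "RRM1", "UNG",
            "GINS2", "MCM6", "CDCA7", "DTL", "PRIM1", "UHRF1", "HELLS",
            "RFC2", "RPA2", "NASP", "RAD51AP1", "GMNN"),
    g2m = c("CDK1", "TOP2A", "UBE2C", "BIRC5", "TPX2", "CCNB1", "CCNB2",
            "AURKA", "AURKB", "BUB1", "KIF11", "PLK1", "CDC20", "MKI67",
            "CENPF", "CENPA", "CENPE", "NUSAP1", "CKS2", "ANLN")
  )
}

mito_gene_names <- function(genome = c("human", "mouse")) {
  genome <- match.arg(genome)
  base <- c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3", "ND4", "ND5", "CYB")
  if (genome == "human") paste0("MT-", base) else paste0("mt-", base)
}

#' Simulation configuration for mixed-species PDX droplet data
#'
#' Defines the data-generating conditions: cell-type sizes and species,
#' genome sizes, sequencing depth, mitochondrial load, cross-species ambient
#' contamination, human+mouse multiplets, chromosome-arm dosage segments for
#' tumor subclones, marker and cell-cycle programs, and a planted
#' ligand-receptor interaction. The defaults describe a PDX-like mixture of
#' ~2000 cells: 500 human tumor cells (one subclone with 30% of human genes
#' at dosage 0.5 or 1.5), 500 human stromal cells, and mouse fibroblasts and
#' macrophages, sequenced to ~5000 UMIs/cell.
#'
#' @param n_cells_per_type named integer vector, cells per type
#' @param cell_type_species named character vector mapping each type to
#'   `"human"` or `"mouse"`
#' @param tumor_types character, which types are malignant (human only)
#' @param n_genes_human,n_genes_mouse genome sizes (incl. markers/mito)
#' @param n_chromosomes autosomes the human genes are split across
#' @param mean_depth expected UMIs per cell
#' @param depth_dispersion sdlog of the lognormal per-cell depth
#' @param nb_size negative-binomial size (inverse overdispersion) per gene
#' @param mito_fraction_normal,mito_fraction_dying expected mitochondrial UMI
#'   fraction for healthy and dying cells
#' @param dying_fraction fraction of cells drawn with the dying mito load
#' @param ambient_cross_species_rate fraction of each cell's depth received
#'   as ambient counts on the other genome
#' @param multiplet_rate fraction of barcodes that are human+mouse doublets
#' @param cnv_segments data frame (chromosome, start_gene, end_gene, dosage,
#'   subclone); gene indices are within-chromosome, segments must not overlap
#'   within a subclone
#' @param marker_genes named list cell-type -> marker gene symbols
#' @param cycle_genes list with `g1s` and `g2m` gene panels (human)
#' @param cycle_program_strength fold-boost of cycle panels in cycling cells
#' @param cycle_fractions tumor-cell fractions c(cycling, noncycling,
#'   intermediate); must sum to 1
#' @param lr_pairs_planted data frame (ligand, receptor, sender, receiver):
#'   ligand boosted in the sender type only, receptor in the receiver only
#' @param seed integer; one seed drives all simulation sub-streams
#'
#' @return a validated `scpdx_sim_config` list
#' @export
sim_config <- function(n_cells_per_type = c(tumor = 500, stromal = 500,
                                            fibroblast = 500, macrophage = 500),
                       cell_type_species = c(tumor = "human", stromal = "human",
                                             fibroblast = "mouse",
                                             macrophage = "mouse",
                                             tcell = "mouse"),
                       tumor_types = "tumor",
                       n_genes_human = 6000,
                       n_genes_mouse = 3000,
                       n_chromosomes = 10,
                       mean_depth = 5000,
                       depth_dispersion = 0.3,
                       nb_size = 2,
                       mito_fraction_normal = 0.05,
                       mito_fraction_dying = 0.15,
                       dying_fraction = 0,
                       ambient_cross_species_rate = 0.005,
                       multiplet_rate = 0.02,
                       cnv_segments = default_cnv_segments(),
                       marker_genes = default_marker_genes(),
                       cycle_genes = default_cycle_genes(),
                       cycle_program_strength = 4,
                       cycle_fractions = c(cycling = 0.4, noncycling = 0.4,
                                           intermediate = 0.2),
                       lr_pairs_planted = tibble(
                         ligand = "CD274", receptor = "Pdcd1",
                         sender = "tumor", receiver = "macrophage"
                       ),
                       seed = 1L) {
  cfg <- list(
    n_cells_per_type = n_cells_per_type,
    cell_type_species = cell_type_species,
    tumor_types = tumor_types,
    n_genes_human = as.integer(n_genes_human),
    n_genes_mouse = as.integer(n_genes_mouse),
    n_chromosomes = as.integer(n_chromosomes),
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    nb_size = nb_size,
    mito_fraction_normal = mito_fraction_normal,
    mito_fraction_dying = mito_fraction_dying,
    dying_fraction = dying_fraction,
    ambient_cross_species_rate = ambient_cross_species_rate,
    multiplet_rate = multiplet_rate,
    cnv_segments = as_tibble(cnv_segments),
    marker_genes = marker_genes,
    cycle_genes = cycle_genes,
    cycle_program_strength = cycle_program_strength,
    cycle_fractions = cycle_fractions,
    lr_pairs_planted = if (is.null(lr_pairs_planted)) NULL else as_tibble(lr_pairs_planted),
    seed = as.integer(seed)
  )
  class(cfg) <- "scpdx_sim_config"
  validate_sim_config(cfg)
}

#' Default tumor-subclone dosage segments
#'
#' One subclone with 30% of the human genome altered: with 10 chromosomes of
#' 600 genes each, genes 1-450 of chromosomes 1 and 3 gained at dosage 1.5
#' and of chromosomes 2 and 4 lost at dosage 0.5 (1800 / 6000 genes).
#' @return tibble (chromosome, start_gene, end_gene, dosage, subclone)
#' @export
default_cnv_segments <- function() {
  tibble(
    chromosome = c("1", "2", "3", "4"),
    start_gene = 1L,
    end_gene = 450L,
    dosage = c(1.5, 0.5, 1.5, 0.5),
    subclone = "clone1"
  )
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$mito_fraction_normal, cfg$mito_fraction_dying,
             cfg$dying_fraction, cfg$ambient_cross_species_rate,
             cfg$multiplet_rate)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (any(cfg$n_cells_per_type < 0)) abort("negative cell counts")
  types <- names(cfg$n_cells_per_type)
  if (is.null(types) || !all(types %in% names(cfg$cell_type_species))) {
    abort("every simulated cell type needs a species in `cell_type_species`")
  }
  if (!all(cfg$cell_type_species %in% c("human", "mouse"))) {
    abort("species must be 'human' or 'mouse'")
  }
  if (!all(cfg$tumor_types %in% types)) abort("unknown tumor type")
  if (any(cfg$cell_type_species[cfg$tumor_types] != "human")) {
    abort("tumor types must be human")
  }
  seg <- cfg$cnv_segments
  if (nrow(seg)) {
    if (any(seg$dosage <= 0)) abort("dosage multipliers must be > 0")
    if (any(seg$start_gene < 1 | seg$end_gene < seg$start_gene)) {
      abort("invalid CNV segment gene indices")
    }
    per_chrom <- ceiling(cfg$n_genes_human / cfg$n_chromosomes)
    if (any(seg$end_gene > per_chrom)) {
      abort("CNV segment exceeds genes on chromosome")
    }
    split(seg, list(seg$subclone, seg$chromosome), drop = TRUE) |>
      lapply(function(s) {
        s <- s[order(s$start_gene), ]
        if (nrow(s) > 1 && any(s$start_gene[-1] <= s$end_gene[-nrow(s)])) {
          abort("CNV segments overlap within one subclone")
        }
      })
  }
  if (abs(sum(cfg$cycle_fractions) - 1) > 1e-8) {
    abort("cycle_fractions must sum to 1")
  }
  hs <- unlist(cfg$marker_genes[types[cfg$cell_type_species[types] == "human"]])
  ms <- unlist(cfg$marker_genes[types[cfg$cell_type_species[types] == "mouse"]])
  if (length(intersect(hs, ms))) {
    abort("marker genes must belong to exactly one genome")
  }
  cfg
}

# deterministic per-stage sub-seed from the one config seed
sub_seed <- function(seed, stage) {
  (as.integer(seed) + 7919L * stage) %% .Machine$integer.max
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Build the gene tables for one genome: named special genes are spread evenly
# through the filler genes so no marker/cycle panel concentrates in one CNV
# window; human genes get contiguous chromosome blocks, mito genes sit on "MT".
build_gene_table <- function(cfg, genome) {
  types <- names(cfg$n_cells_per_type)
  own <- types[cfg$cell_type_species[types] == (if (genome == "human") "human" else "mouse")]
  special <- unique(unlist(cfg$marker_genes[own], use.names = FALSE))
  if (genome == "human") {
    special <- unique(c(special, cfg$cycle_genes$g1s, cfg$cycle_genes$g2m,
                        "ACTB", "GAPDH"))
  } else {
    special <- unique(c(special, "Actb", "Gapdh"))
  }
  if (!is.null(cfg$lr_pairs_planted) && nrow(cfg$lr_pairs_planted)) {
    lr <- cfg$lr_pairs_planted
    lg <- lr$ligand[cfg$cell_type_species[lr$sender] == (if (genome == "human") "human" else "mouse")]
    rg <- lr$receptor[cfg$cell_type_species[lr$receiver] == (if (genome == "human") "human" else "mouse")]
    special <- unique(c(special, lg, rg))
  }
  mito <- mito_gene_names(genome)
  n <- if (genome == "human") cfg$n_genes_human else cfg$n_genes_mouse
  n_body <- n - length(mito)
  if (n_body < length(special) + 10) abort("genome too small for its named genes")
  prefix <- if (genome == "human") "GH" else "GM"
  name <- paste0(prefix, formatC(seq_len(n_body), width = 5, flag = "0"))
  slots <- round(seq(1, n_body, length.out = length(special)))
  name[slots] <- special
  name <- c(name, mito)
  if (genome == "human") {
    per_chrom <- ceiling(n_body / cfg$n_chromosomes)
    chrom <- as.character(rep(seq_len(cfg$n_chromosomes), each = per_chrom)[seq_len(n_body)])
    pos_in_chrom <- stats::ave(seq_len(n_body), chrom, FUN = seq_along)
    chrom <- c(chrom, rep("MT", length(mito)))
    start <- c(pos_in_chrom * 1000L, seq_along(mito) * 100L)
  } else {
    chrom <- rep(NA_character_, n)
    start <- rep(NA_integer_, n)
  }
  tibble(
    gene_id = paste0(if (genome == "human") "ENSGS" else "ENSMUSGS",
                     formatC(seq_len(n), width = 6, flag = "0")),
    gene_name = name,
    genome = if (genome == "human") "GRCh38" else "mm10",
    chromosome = chrom,
    start = as.integer(start)
  )
}

# expression program (relative weights over one genome's non-mito genes)
build_programs <- function(cfg, genes, genome) {
  types <- names(cfg$n_cells_per_type)
  own <- types[cfg$cell_type_species[types] == genome]
  body <- !(genes$chromosome %in% "MT") & !startsWith(genes$gene_name, "mt-")
  n <- nrow(genes)
  base <- rlnorm(n, meanlog = 0, sdlog = 1.2)
  base[!body] <- 0
  # cycle-program genes get a fixed moderate base weight: canonical
  # proliferation genes are consistently expressed, not drawn from the
  # heavy-tailed distribution of arbitrary genes
  cyc <- genes$gene_name %in% unlist(cfg$cycle_genes)
  base[cyc] <- mean(base[body])
  hk <- genes$gene_name %in% c("ACTB", "GAPDH", "Actb", "Gapdh")
  programs <- list()
  for (ty in own) {
    w <- base
    for (other in setdiff(own, ty)) {
      w[genes$gene_name %in% cfg$marker_genes[[other]]] <- w[genes$gene_name %in% cfg$marker_genes[[other]]] * 0.02
    }
    w[genes$gene_name %in% cfg$marker_genes[[ty]]] <- base[genes$gene_name %in% cfg$marker_genes[[ty]]] * 25
    if (!is.null(cfg$lr_pairs_planted) && nrow(cfg$lr_pairs_planted)) {
      for (i in seq_len(nrow(cfg$lr_pairs_planted))) {
        p <- cfg$lr_pairs_planted[i, ]
        if (p$ligand %in% genes$gene_name) {
          w[genes$gene_name == p$ligand] <- if (identical(p$sender, ty))
            mean(base[body]) * 20 else 0
        }
        if (p$receptor %in% genes$gene_name) {
          w[genes$gene_name == p$receptor] <- if (identical(p$receiver, ty))
            mean(base[body]) * 20 else 0
        }
      }
    }
    # pin the two housekeeping genes to ~1.5% of depth each
    w[hk] <- 0
    w[hk] <- sum(w) * 0.015 / (1 - 2 * 0.015)
    programs[[ty]] <- w / sum(w)
  }
  programs
}

#' Simulate a mixed-species PDX droplet experiment
#'
#' Draws UMI counts per cell from a negative binomial around a cell-type
#' expression program scaled by a lognormal per-cell depth. Tumor cells'
#' expected expression is multiplied gene-wise by their subclone's dosage
#' profile (no renormalization, so a dosage d multiplies the expected count
#' by d exactly). Mitochondrial genes receive the configured fraction of
#' depth; every cell leaks `ambient_cross_species_rate` of its depth onto the
#' other genome; a `multiplet_rate` fraction of barcodes additionally contain
#' a whole cell of the other species. Cycling tumor cells have both cell-cycle
#' panels boosted; non-cycling cells have them damped. Fully reproducible
#' from `config$seed`.
#'
#' @param config a [sim_config()]
#' @return list with `experiment` (a [pdx_experiment()]), `truth` (tibble:
#'   barcode, species, cell_type, malignant, cycle_state, subclone) and
#'   `gene_dosage` (tibble: gene_id, subclone, dosage)
#' @export
simulate_mixed_pdx <- function(config) {
  stopifnot(inherits(config, "scpdx_sim_config"))
  cfg <- validate_sim_config(config)
  genes_h <- with_seed(sub_seed(cfg$seed, 1L), build_gene_table(cfg, "human"))
  genes_m <- with_seed(sub_seed(cfg$seed, 2L), build_gene_table(cfg, "mouse"))
  genes <- bind_rows(genes_h, genes_m)
  prog_h <- with_seed(sub_seed(cfg$seed, 3L), build_programs(cfg, genes_h, "human"))
  prog_m <- with_seed(sub_seed(cfg$seed, 4L), build_programs(cfg, genes_m, "mouse"))

  types <- names(cfg$n_cells_per_type)
  cell_type <- rep(types, times = cfg$n_cells_per_type)
  n_cells <- length(cell_type)
  species <- unname(cfg$cell_type_species[cell_type])
  malignant <- cell_type %in% cfg$tumor_types

  # per-subclone dosage vectors over human genes
  subclones <- unique(cfg$cnv_segments$subclone)
  per_chrom_idx <- stats::ave(seq_len(nrow(genes_h)), genes_h$chromosome, FUN = seq_along)
  dosage_of <- function(sc) {
    d <- rep(1, nrow(genes_h))
    seg <- cfg$cnv_segments[cfg$cnv_segments$subclone == sc, ]
    for (i in seq_len(nrow(seg))) {
      hit <- genes_h$chromosome == seg$chromosome[i] &
        per_chrom_idx >= seg$start_gene[i] & per_chrom_idx <= seg$end_gene[i]
      d[hit] <- seg$dosage[i]
    }
    d
  }
  dosages <- lapply(setNames(subclones, subclones), dosage_of)
  gene_dosage <- purrr::imap_dfr(dosages, function(d, sc) {
    tibble(gene_id = genes_h$gene_id, subclone = sc, dosage = d)
  })

  truth <- with_seed(sub_seed(cfg$seed, 5L), {
    subclone <- rep(NA_character_, n_cells)
    if (length(subclones) && any(malignant)) {
      subclone[malignant] <- sample(subclones, sum(malignant), replace = TRUE)
    }
    cyc <- rep("non-cycling", n_cells)
    for (ty in cfg$tumor_types) {
      idx <- which(cell_type == ty)
      cyc[idx] <- sample(c("cycling", "non-cycling", "intermediate"),
                         length(idx), replace = TRUE,
                         prob = cfg$cycle_fractions)
    }
    dying <- runif(n_cells) < cfg$dying_fraction
    tibble(cell_type = cell_type, species = species, malignant = malignant,
           subclone = subclone, cycle_state = cyc, dying = dying)
  })

  counts <- with_seed(sub_seed(cfg$seed, 6L), {
    depth <- rlnorm(n_cells, log(cfg$mean_depth) - cfg$depth_dispersion^2 / 2,
                    cfg$depth_dispersion)
    mito_h <- genes_h$chromosome %in% "MT"
    mito_m <- startsWith(genes_m$gene_name, "mt-")
    cyc_h <- list(
      g1s = genes_h$gene_name %in% cfg$cycle_genes$g1s,
      g2m = genes_h$gene_name %in% cfg$cycle_genes$g2m
    )
    draw_cell <- function(ty, sp, sc, cyc_state, dying, d) {
      if (sp == "human") {
        w <- prog_h[[ty]]; mito <- mito_h; n_g <- nrow(genes_h)
      } else {
        w <- prog_m[[ty]]; mito <- mito_m; n_g <- nrow(genes_m)
      }
      f <- if (dying) cfg$mito_fraction_dying else cfg$mito_fraction_normal
      mu <- (1 - f) * d * w
      mu[mito] <- f * d / sum(mito)
      if (sp == "human") {
        if (!is.na(sc)) mu <- mu * dosages[[sc]]
        s <- cfg$cycle_program_strength
        if (cyc_state == "cycling") {
          mu[cyc_h$g1s | cyc_h$g2m] <- mu[cyc_h$g1s | cyc_h$g2m] * s
        } else if (cyc_state == "non-cycling") {
          mu[cyc_h$g1s | cyc_h$g2m] <- mu[cyc_h$g1s | cyc_h$g2m] / s
        } else {
          mu[cyc_h$g2m] <- mu[cyc_h$g2m] * s
          mu[cyc_h$g1s] <- mu[cyc_h$g1s] / s
        }
      }
      rnbinom(n_g, size = cfg$nb_size, mu = mu)
    }
    nh <- nrow(genes_h); nm <- nrow(genes_m)
    mat <- matrix(0L, nrow = nh + nm, ncol = n_cells)
    for (i in seq_len(n_cells)) {
      v <- draw_cell(truth$cell_type[i], truth$species[i], truth$subclone[i],
                     truth$cycle_state[i], truth$dying[i], depth[i])
      if (truth$species[i] == "human") mat[seq_len(nh), i] <- v
      else mat[nh + seq_len(nm), i] <- v
    }
    # ambient cross-species contamination: a Poisson share of depth spread
    # over the other genome's average program
    if (cfg$ambient_cross_species_rate > 0) {
      amb_h <- rowMeans(do.call(cbind, prog_h))
      amb_m <- if (length(prog_m)) rowMeans(do.call(cbind, prog_m)) else NULL
      for (i in seq_len(n_cells)) {
        tot <- stats::rpois(1, cfg$ambient_cross_species_rate * depth[i])
        if (tot == 0) next
        if (truth$species[i] == "human" && !is.null(amb_m)) {
          mat[nh + seq_len(nm), i] <- mat[nh + seq_len(nm), i] +
            as.integer(rmultinom(1, tot, amb_m))
        } else if (truth$species[i] == "mouse") {
          mat[seq_len(nh), i] <- mat[seq_len(nh), i] +
            as.integer(rmultinom(1, tot, amb_h))
        }
      }
    }
    # human+mouse doublets: add a whole other-species cell to some barcodes
    if (cfg$multiplet_rate > 0) {
      n_mult <- round(cfg$multiplet_rate * n_cells)
      if (n_mult > 0) {
        pick <- sample(n_cells, n_mult)
        for (i in pick) {
          other_sp <- if (truth$species[i] == "human") "mouse" else "human"
          cand <- types[cfg$cell_type_species[types] == other_sp]
          if (!length(cand)) next
          ty2 <- sample(cand, 1)
          d2 <- rlnorm(1, log(cfg$mean_depth) - cfg$depth_dispersion^2 / 2,
                       cfg$depth_dispersion)
          v <- draw_cell(ty2, other_sp, NA_character_, "non-cycling", FALSE, d2)
          if (other_sp == "human") mat[seq_len(nh), i] <- mat[seq_len(nh), i] + v
          else mat[nh + seq_len(nm), i] <- mat[nh + seq_len(nm), i] + v
          truth$species[i] <- "multiplet"
        }
      }
    }
    mat
  })
  stopifnot(is.matrix(counts))

  barcode <- sprintf("BC%05d-1", seq_len(n_cells))
  truth <- bind_cols(tibble(barcode = barcode), truth)
  exp <- pdx_experiment(counts, genes, tibble(barcode = barcode))
  list(experiment = exp,
       truth = select(truth, "barcode", "species", "cell_type", "malignant",
                      "cycle_state", "subclone"),
       gene_dosage = gene_dosage,
       config = cfg)
}
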