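#' Parameters for expression-derived CNV inference
#'
#' @param low_expression_mean_min genes with mean normalized expression below
#'   this are discarded (default 0.2)
#' @param clip_abs standardized expression is clipped to +/- this (default 3)
#' @param window_genes moving-average window, in genes (default 100)
#' @param top_score_fraction fraction of top-scoring cells defining the
#'   putative-malignant reference profile (default 5%)
#' @param score_cutoff CNV-score cutoff (default 0.02)
#' @param correlation_cutoff CNV-correlation cutoff (default 0.2)
#' @param chromosome_order karyotype order used to sort genes; chromosomes
#'   not listed sort after, alphabetically
#' @return a `scpdx_cnv_params` list
#' @export
cnv_params <- function(low_expression_mean_min = 0.2, clip_abs = 3,
                       window_genes = 100, top_score_fraction = 0.05,
                       score_cutoff = 0.02, correlation_cutoff = 0.2,
                       chromosome_order = c(as.character(1:22), "X", "Y")) {
  stopifnot(window_genes >= 1, top_score_fraction > 0, top_score_fraction <= 1,
            score_cutoff > 0, correlation_cutoff > 0, clip_abs > 0)
  structure(
    list(low_expression_mean_min = low_expression_mean_min,
         clip_abs = clip_abs, window_genes = as.integer(window_genes),
         top_score_fraction = top_score_fraction,
         score_cutoff = score_cutoff,
         correlation_cutoff = correlation_cutoff,
         chromosome_order = chromosome_order),
    class = "scpdx_cnv_params"
  )
}

order_chromosomes <- function(chrom, params) {
  known <- match(chrom, params$chromosome_order)
  known[is.na(known)] <- length(params$chromosome_order) + 1L
  known
}

#' Prepare expression for CNV inference
#'
#' Drops genes without a position (with a warning) and genes whose mean
#' normalized expression is below the low-expression floor; standardizes
#' each remaining gene (center and unit variance in one pass — centering is
#' idempotent, so the separate centering and z-scoring steps collapse;
#' zero-variance genes become all-zero); clips to +/- `clip_abs` (clipping
#' precedes windowing so single extreme values cannot distort the moving
#' average); and orders genes by (chromosome, start) in karyotype order.
#'
#' With `baseline_cells` given (typically stromal/immune cells identified by
#' marker annotation before CNV inference), each gene is centered and scaled
#' on those presumed-diploid cells instead of on all cells. This anchors the
#' zero point of the inferred CNVs at the normal karyotype: without an
#' anchor, a sample whose malignant fraction approaches half leaves the
#' all-cell mean midway between the two populations and the sign of the
#' inferred profile — hence which population looks "distorted" — is decided
#' by noise.
#'
#' @param exp a normalized [pdx_experiment()]
#' @param positions optional tibble (gene_id, chromosome, start); defaults to
#'   the experiment's own gene table
#' @param params a [cnv_params()]
#' @param baseline_cells optional barcodes of presumed-normal cells used as
#'   the centering/scaling reference
#' @return a `scpdx_cnv_prep`: `matrix` (ordered genes x cells) and `genes`
#'   tibble
#' @export
prepare_expression <- function(exp, positions = NULL, params = cnv_params(),
                               baseline_cells = NULL) {
  m <- norm_matrix(exp)
  genes <- exp$genes
  if (!is.null(positions)) {
    genes <- genes[, setdiff(names(genes), c("chromosome", "start"))]
    genes <- left_join(genes, positions[, c("gene_id", "chromosome", "start")],
                       by = "gene_id")
  }
  if (!all(c("chromosome", "start") %in% names(genes))) {
    abort("no gene positions available; supply `positions`")
  }
  unpos <- is.na(genes$chromosome) | is.na(genes$start)
  if (any(unpos)) {
    warn(sprintf("dropping %d gene(s) without position", sum(unpos)))
  }
  mu <- Matrix::rowMeans(m)
  keep <- !unpos & mu >= params$low_expression_mean_min
  if (!any(keep)) abort("no gene passes the low-expression filter")
  genes <- genes[keep, ]
  x <- as.matrix(m[keep, , drop = FALSE])
  if (is.null(baseline_cells)) {
    base_cols <- seq_len(ncol(x))
  } else {
    base_cols <- match(baseline_cells, exp$cells$barcode)
    if (anyNA(base_cols)) abort("unknown barcodes in `baseline_cells`")
    if (length(base_cols) < 2) abort("need >= 2 baseline cells")
  }
  mu <- rowMeans(x[, base_cols, drop = FALSE])
  sdv <- apply(x[, base_cols, drop = FALSE], 1, sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z[z > params$clip_abs] <- params$clip_abs
  z[z < -params$clip_abs] <- -params$clip_abs
  ord <- order(order_chromosomes(genes$chromosome, params), genes$start)
  genes <- genes[ord, ]
  z <- z[ord, , drop = FALSE]
  n_per_chrom <- table(genes$chromosome)
  if (all(n_per_chrom < params$window_genes)) {
    abort(sprintf("every chromosome has fewer than %d genes; cannot window",
                  params$window_genes))
  }
  structure(list(matrix = z, genes = genes, params = params),
            class = "scpdx_cnv_prep")
}

# centered moving-average over one chromosome block, truncated at the ends
running_mean <- function(block, w) {
  g <- nrow(block)
  cs <- apply(block, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = g)
  half_lo <- floor((w - 1) / 2)
  half_hi <- ceiling((w - 1) / 2)
  lo <- pmax(seq_len(g) - half_lo, 1L)
  hi <- pmin(seq_len(g) + half_hi, g)
  top <- cs[hi, , drop = FALSE]
  bottom <- rbind(0, cs)[lo, , drop = FALSE]
  (top - bottom) / (hi - lo + 1)
}

#' Moving-average CNV smoothing
#'
#' Per chromosome, per cell, the sliding mean over `window_genes` consecutive
#' position-ordered genes (step 1, window truncated at chromosome ends,
#' never spanning chromosomes); afterwards each cell's profile is re-centered
#' to mean zero.
#'
#' @param prep a `scpdx_cnv_prep` from [prepare_expression()]
#' @return a `scpdx_cnv_prep` whose matrix holds inferred CNV values
#' @export
moving_average <- function(prep) {
  stopifnot(inherits(prep, "scpdx_cnv_prep"))
  w <- prep$params$window_genes
  chrom <- prep$genes$chromosome
  out <- prep$matrix
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    out[rows, ] <- running_mean(prep$matrix[rows, , drop = FALSE], w)
  }
  out <- sweep(out, 2, colMeans(out))
  prep$matrix <- out
  prep$windowed <- TRUE
  prep
}

#' CNV score of a profile
#'
#' The mean of squared inferred-CNV values: for a vector, a scalar; for a
#' genes x cells matrix, one score per cell.
#'
#' @param x numeric vector (one cell's profile) or genes x cells matrix
#' @return nonnegative numeric
#' @export
cnv_score <- function(x) {
  if (is.matrix(x)) colMeans(x^2) else mean(x^2)
}

#' The two-cutoff malignancy decision rule
#'
#' Tumor when CNV score and CNV correlation are both strictly above their
#' cutoffs; non-tumor when both are strictly below; undetermined otherwise —
#' discordant pairs, values exactly at a cutoff, and undefined correlations.
#'
#' @param score numeric CNV scores
#' @param correlation numeric CNV correlations (NA allowed)
#' @param params a [cnv_params()]
#' @return character vector: "tumor", "non-tumor" or "undetermined"
#' @export
cnv_call_rule <- function(score, correlation, params = cnv_params()) {
  dplyr::case_when(
    is.na(correlation) ~ "undetermined",
    score > params$score_cutoff & correlation > params$correlation_cutoff ~ "tumor",
    score < params$score_cutoff & correlation < params$correlation_cutoff ~ "non-tumor",
    TRUE ~ "undetermined"
  )
}

#' Call malignancy from CNV score and CNV correlation
#'
#' The reference profile is the per-gene mean of inferred CNV over the cells
#' in the top `top_score_fraction` by CNV score (taken once, from the
#' pre-call ranking); each cell's CNV correlation is its Pearson r against
#' that profile. Cells with both values strictly above the two cutoffs are
#' tumor; both strictly below, non-tumor; anything else (including values
#' exactly at a cutoff) is undetermined.
#'
#' @param prep a windowed `scpdx_cnv_prep` from [moving_average()]
#' @return a `scpdx_cnv` object: `matrix`, `genes`, `calls` tibble (barcode,
#'   cnv_score, cnv_correlation, call), `reference`, `recalibrated`
#' @export
malignancy_call <- function(prep) {
  stopifnot(inherits(prep, "scpdx_cnv_prep"), isTRUE(prep$windowed))
  params <- prep$params
  m <- prep$matrix
  scores <- cnv_score(m)
  n_ref <- max(1L, ceiling(params$top_score_fraction * length(scores)))
  ref_cells <- order(scores, decreasing = TRUE)[seq_len(n_ref)]
  reference <- rowMeans(m[, ref_cells, drop = FALSE])
  if (sd(reference) == 0) {
    warn("reference CNV profile is constant; correlation undefined, all calls undetermined")
    corr <- rep(NA_real_, ncol(m))
  } else {
    corr <- as.numeric(cor(m, reference))
  }
  call <- cnv_call_rule(scores, corr, params)
  structure(
    list(matrix = m, genes = prep$genes,
         calls = tibble(barcode = colnames(m), cnv_score = scores,
                        cnv_correlation = corr, call = call),
         reference = reference, params = params, recalibrated = FALSE),
    class = "scpdx_cnv"
  )
}

#' Recalibrate inferred CNVs against the non-tumor cells
#'
#' Subtracts the per-gene mean of the non-tumor cells from every cell's
#' inferred CNV, then recomputes scores, reference profile, correlations and
#' calls once on the recalibrated matrix. With no non-tumor cells the input
#' is returned flagged uncalibrated, with a warning.
#'
#' @param result a `scpdx_cnv` from [malignancy_call()]
#' @return a recalibrated `scpdx_cnv`
#' @export
recalibrate <- function(result) {
  stopifnot(inherits(result, "scpdx_cnv"))
  nt <- result$calls$call == "non-tumor"
  if (!any(nt)) {
    warn("no non-tumor cells; CNV result left uncalibrated")
    result$recalibrated <- FALSE
    return(result)
  }
  baseline <- rowMeans(result$matrix[, nt, drop = FALSE])
  prep <- structure(
    list(matrix = result$matrix - baseline, genes = result$genes,
         params = result$params, windowed = TRUE),
    class = "scpdx_cnv_prep"
  )
  out <- malignancy_call(prep)
  out$recalibrated <- TRUE
  out$baseline_barcodes <- result$calls$barcode[nt]
  out
}

#' Full expression-derived CNV inference
#'
#' [prepare_expression()], [moving_average()], [malignancy_call()] and one
#' pass of [recalibrate()], in order.
#'
#' @inheritParams prepare_expression
#' @param recalibrate_result run the recalibration pass (default TRUE)
#' @return a `scpdx_cnv`
#' @export
infer_cnv <- function(exp, positions = NULL, params = cnv_params(),
                      baseline_cells = NULL, recalibrate_result = TRUE) {
  prep <- prepare_expression(exp, positions, params,
                             baseline_cells = baseline_cells)
  res <- malignancy_call(moving_average(prep))
  if (recalibrate_result) res <- recalibrate(res)
  res
}

#' @method print scpdx_cnv
#' @export
print.scpdx_cnv <- function(x, ...) {
  cat(sprintf("<scpdx_cnv> %d cells x %d genes%s\n", ncol(x$matrix),
              nrow(x$matrix), if (x$recalibrated) ", recalibrated" else ""))
  print(count(x$calls, .data$call))
  invisible(x)
}

#' @method tidy scpdx_cnv
#' @export
tidy.scpdx_cnv <- function(x, ...) x$calls

#' @method glance scpdx_cnv
#' @export
glance.scpdx_cnv <- function(x, ...) {
  tibble(
    n_cells = nrow(x$calls),
    n_tumor = sum(x$calls$call == "tumor"),
    n_non_tumor = sum(x$calls$call == "non-tumor"),
    n_undetermined = sum(x$calls$call == "undetermined"),
    recalibrated = x$recalibrated
  )
}

#' @rdname autoplot_scpdx
#' @method autoplot scpdx_cnv
#' @export
autoplot.scpdx_cnv <- function(object, ...) {
  ggplot(object$calls, aes(x = .data$cnv_score, y = .data$cnv_correlation,
                           colour = .data$call)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_vline(xintercept = object$params$score_cutoff, linetype = 2) +
    geom_hline(yintercept = object$params$correlation_cutoff, linetype = 2) +
    labs(x = "CNV score (mean of squared inferred CNV)",
         y = "CNV correlation (r vs reference profile)", colour = "call") +
    theme_bw()
}
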