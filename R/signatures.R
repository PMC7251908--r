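#' Rank-based gene-set enrichment score
#'
#' Per cell, genes are ranked by expression (average ranks on ties); the
#' score is the difference between the mean rank of in-set genes and the
#' mean rank of out-set genes, rescaled to [-1, 1] (division by n/2, the
#' largest attainable difference for any set size). Positive scores mean
#' the set is enriched among the cell's most highly expressed genes. Being
#' rank-based, the score is invariant to any monotone per-cell transform of
#' expression.
#'
#' @param exp a normalized [pdx_experiment()], or a genes x cells numeric
#'   matrix with gene names as rownames
#' @param genes gene names in the set; genes absent from the matrix are
#'   dropped with a warning
#' @return named numeric vector of per-cell scores
#' @export
score_gene_set <- function(exp, genes) {
  if (inherits(exp, "pdx_experiment")) {
    m <- norm_matrix(exp)
    gene_names <- exp$genes$gene_name
  } else {
    m <- exp
    gene_names <- rownames(m)
  }
  in_set <- gene_names %in% genes
  n_missing <- length(unique(genes)) - sum(unique(genes) %in% gene_names)
  if (n_missing > 0) warn(sprintf("%d gene(s) of the set absent from the matrix",
                                  n_missing))
  if (!any(in_set)) abort("no gene of the set present in the matrix")
  if (all(in_set)) abort("gene set covers every gene; score undefined")
  n <- nrow(m)
  dense <- as.matrix(m)
  scores <- apply(dense, 2, function(v) {
    r <- rank(v)
    (mean(r[in_set]) - mean(r[!in_set])) / (n / 2)
  })
  setNames(scores, colnames(m))
}

#' Classify cell-cycle state from phase scores
#'
#' Cycling if both the G1/S and the G2/M score are strictly positive,
#' non-cycling if both are strictly negative, intermediate otherwise
#' (discordant signs and exact zeros).
#'
#' @param g1s_score,g2m_score numeric vectors of phase scores
#' @return character vector: "cycling", "non-cycling" or "intermediate"
#' @export
classify_cycle <- function(g1s_score, g2m_score) {
  stopifnot(length(g1s_score) == length(g2m_score),
            all(is.finite(g1s_score)), all(is.finite(g2m_score)))
  dplyr::case_when(
    g1s_score > 0 & g2m_score > 0 ~ "cycling",
    g1s_score < 0 & g2m_score < 0 ~ "non-cycling",
    TRUE ~ "intermediate"
  )
}

#' Per-cell cell-cycle scoring and state
#'
#' @param exp a normalized [pdx_experiment()]
#' @param cycle_genes list with `g1s` and `g2m` gene-name panels (default
#'   [default_cycle_genes()])
#' @return tibble (barcode, g1s_score, g2m_score, cycle_state)
#' @export
cycle_scores <- function(exp, cycle_genes = default_cycle_genes()) {
  g1s <- score_gene_set(exp, cycle_genes$g1s)
  g2m <- score_gene_set(exp, cycle_genes$g2m)
  tibble(barcode = exp$cells$barcode, g1s_score = unname(g1s),
         g2m_score = unname(g2m),
         cycle_state = classify_cycle(g1s, g2m))
}

#' Assign molecular subtype by signature correlation
#'
#' Each sample is correlated (Pearson, two-sided p) against each subtype
#' centroid over the centroid's signature genes; the assigned subtype is the
#' arg-max r among subtypes with positive r and p below `alpha`, or
#' "unclassified" when none qualifies (anti-correlation is never a call). Subtypes sharing fewer than `min_shared` genes with
#' the sample are skipped with a warning; exact r ties break by centroid
#' column order with a warning.
#'
#' @param profile named numeric vector (one sample), or a genes x samples
#'   matrix / data frame with gene rownames
#' @param centroids genes x subtypes matrix or data frame (gene rownames or
#'   a `gene` column)
#' @param min_shared minimum shared signature genes per subtype
#' @param alpha significance level for the correlation p-value
#' @return a `scpdx_subtype` tibble (sample, subtype, r, p.value,
#'   significant, assigned)
#' @export
assign_subtype <- function(profile, centroids, min_shared = 3, alpha = 0.05) {
  if (is.data.frame(centroids)) {
    if ("gene" %in% names(centroids)) {
      rn <- centroids$gene
      centroids <- as.matrix(centroids[, setdiff(names(centroids), "gene")])
      rownames(centroids) <- rn
    } else centroids <- as.matrix(centroids)
  }
  if (is.null(dim(profile))) profile <- as.matrix(profile)
  if (is.data.frame(profile)) profile <- as.matrix(profile)
  if (is.null(colnames(profile))) {
    colnames(profile) <- paste0("sample", seq_len(ncol(profile)))
  }
  subtypes <- colnames(centroids)
  out <- purrr::map_dfr(colnames(profile), function(s) {
    v <- profile[, s]
    rows <- purrr::map_dfr(subtypes, function(st) {
      cen <- centroids[, st]
      shared <- intersect(names(cen)[!is.na(cen)], names(v)[!is.na(v)])
      if (length(shared) < min_shared) {
        warn(sprintf("subtype %s shares %d < %d genes with sample %s; skipped",
                     st, length(shared), min_shared, s))
        return(tibble(sample = s, subtype = st, r = NA_real_,
                      p.value = NA_real_))
      }
      ct <- stats::cor.test(v[shared], cen[shared])
      tibble(sample = s, subtype = st, r = unname(ct$estimate),
             p.value = ct$p.value)
    })
    rows$significant <- !is.na(rows$p.value) & rows$p.value < alpha
    cand <- which(rows$significant & rows$r > 0)
    if (!length(cand)) {
      rows$assigned <- FALSE
      return(mutate(rows, call = "unclassified"))
    }
    best <- cand[rows$r[cand] == max(rows$r[cand])]
    if (length(best) > 1) {
      warn(paste0("tied subtype correlations for sample ", s,
                  "; first in centroid order assigned"))
      best <- best[1]
    }
    rows$assigned <- seq_len(nrow(rows)) == best
    mutate(rows, call = rows$subtype[best])
  })
  class(out) <- c("scpdx_subtype", class(out))
  out
}

#' Summarise subtype calls
#'
#' @param x a `scpdx_subtype` from [assign_subtype()]
#' @param ... unused
#' @return tibble (sample, call, r, p.value): one row per sample
#' @method glance scpdx_subtype
#' @export
glance.scpdx_subtype <- function(x, ...) {
  x %>%
    group_by(.data$sample) %>%
    summarise(
      call = first(.data$call),
      r = ifelse(any(.data$assigned), .data$r[.data$assigned][1], NA_real_),
      p.value = ifelse(any(.data$assigned), .data$p.value[.data$assigned][1],
                       NA_real_),
      .groups = "drop"
    )
}

#' Chi-squared test for cell-composition shifts
#'
#' Pearson chi-squared (no continuity correction) on the 2 x k table of
#' per-category cell counts in two groups; df = k - 1.
#'
#' @param counts_a,counts_b named numeric vectors of per-category cell
#'   counts; names must agree
#' @return tibble (statistic, df, p.value, method)
#' @export
composition_test <- function(counts_a, counts_b) {
  if (!is.null(names(counts_a)) && !is.null(names(counts_b))) {
    cats <- union(names(counts_a), names(counts_b))
    counts_a <- setNames(ifelse(cats %in% names(counts_a), counts_a[cats], 0), cats)
    counts_b <- setNames(ifelse(cats %in% names(counts_b), counts_b[cats], 0), cats)
  }
  if (length(counts_a) != length(counts_b)) abort("category sets must match")
  if (length(counts_a) < 2) abort("need at least 2 categories")
  if (sum(counts_a) <= 0 || sum(counts_b) <= 0) abort("group totals must be > 0")
  tab <- rbind(a = counts_a, b = counts_b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    abort("a category has expected count 0; merge sparse categories")
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p.value = res$p.value, method = "Pearson chi-squared")
}
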