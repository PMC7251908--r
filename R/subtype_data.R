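#' Bundled synthetic subtype centroids
#'
#' A small synthetic stand-in for published bladder-cancer subtype signature
#' centroids (five subtypes, 40 signature genes), bundled so the subtyping
#' workflow can be demonstrated and tested without external signature
#' files. Real analyses should supply their own centroid table (genes x
#' subtypes TSV with a `gene` column).
#'
#' @return genes x subtypes numeric matrix with gene rownames
#' @export
synthetic_subtype_centroids <- function() {
  path <- system.file("extdata", "subtype_centroids_synthetic.tsv",
                      package = "scpdx")
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$gene
  m
}
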