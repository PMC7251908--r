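#' Plot methods for pipeline results
#'
#' `autoplot()` methods: the CNV score/correlation plane with the two
#' calling cutoffs for `scpdx_cnv`, and a faceted sender/receiver dot plot
#' for `scpdx_network`.
#'
#' @param object a result object
#' @param ... unused
#' @return a ggplot
#' @name autoplot_scpdx
NULL

#' Cell-cycle state scatter plot
#'
#' G1/S vs G2/M scores, coloured by the assigned state; the axes at zero are
#' the classification boundaries.
#'
#' @param scores tibble from [cycle_scores()]
#' @return a ggplot
#' @export
plot_cycle_states <- function(scores) {
  ggplot(scores, aes(x = .data$g1s_score, y = .data$g2m_score,
                     colour = .data$cycle_state)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_hline(yintercept = 0, linetype = 2) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "G1/S score", y = "G2/M score", colour = "state") +
    theme_bw()
}

#' Cell-composition comparison bar plot
#'
#' Relative per-category composition of two groups, the quantity the
#' chi-squared composition test compares.
#'
#' @param counts_a,counts_b named per-category cell counts
#' @param group_names labels for the two groups
#' @return a ggplot
#' @export
plot_composition <- function(counts_a, counts_b,
                             group_names = c("group A", "group B")) {
  df <- bind_rows(
    tibble(group = group_names[1], category = names(counts_a),
           fraction = as.numeric(counts_a) / sum(counts_a)),
    tibble(group = group_names[2], category = names(counts_b),
           fraction = as.numeric(counts_b) / sum(counts_b))
  )
  ggplot(df, aes(x = .data$group, y = .data$fraction, fill = .data$category)) +
    geom_col() +
    labs(x = NULL, y = "fraction of cells", fill = NULL) +
    theme_bw()
}
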