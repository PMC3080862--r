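# ggplot2 helpers for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_col geom_line
#'   facet_wrap labs theme_bw geom_hline
#' @export
ggplot2::autoplot

#' @export
autoplot.island_set <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$start, xend = .data$end,
                 y = -log10(.data$q_value),
                 yend = -log10(.data$q_value))) +
    geom_segment(linewidth = 2) +
    facet_wrap(~chrom, ncol = 1) +
    labs(x = "position (bp)", y = "-log10 q-value",
         title = "Enriched islands") +
    theme_bw()
}

#' @export
autoplot.pattern_table <- function(object, ...) {
  df <- as_tibble(object) %>% filter(!is.na(.data$category))
  ggplot(df, aes(x = factor(.data$category), y = .data$n_genes)) +
    geom_col() +
    labs(x = "transition category", y = "genes",
         title = "Bivalency-resolution categories") +
    theme_bw()
}

#' @export
autoplot.position_profile <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$bin_mid / 1000, y = .data$fraction,
             colour = .data$expr_class)) +
    geom_line() +
    facet_wrap(~direction) +
    labs(x = "distance from TSS (kb)", y = "fraction of linked genes",
         colour = "expression class") +
    theme_bw()
}

#' @export
autoplot.enrichment_scan <- function(object, ...) {
  df <- as_tibble(object) %>% filter(.data$testable)
  df$pattern <- paste(df$region, df$dmr_direction, df$expr_class,
                      paste0("K27:", df$k27_cell_type), sep = " / ")
  ggplot(df, aes(x = stats::reorder(.data$pattern, -log10(.data$p_value)),
                 y = -log10(.data$p_value))) +
    geom_col() +
    geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "-log10 Fisher p",
         title = "Joint-pattern enrichment") +
    theme_bw()
}

#' Bar chart of four-state chromatin counts per cell type
#'
#' @param states [classify_states()] output.
#' @return A ggplot object.
#' @export
plot_state_counts <- function(states) {
  df <- count(states, .data$cell_type, .data$state)
  ggplot(df, aes(x = .data$cell_type, y = .data$n, fill = .data$state)) +
    geom_col(position = "stack") +
    labs(x = NULL, y = "genes", fill = "chromatin state") +
    theme_bw()
}
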