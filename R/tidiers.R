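# broom-style tidy()/glance() methods for the pipeline's result objects.

#' @export
tidy.island_set <- function(x, ...) as_tibble(x)

#' @export
glance.island_set <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_islands = nrow(x),
         total_span = sum(x$end - x$start),
         median_length = if (nrow(x)) median(x$end - x$start) else NA_real_,
         lambda_bg = attr(x, "lambda_bg"),
         l0 = attr(x, "l0"),
         n_candidates = attr(x, "n_candidates"),
         window_size = p$window_size, gap_size = p$gap_size,
         fdr_cutoff = p$fdr_cutoff)
}

#' @export
tidy.bloc_set <- function(x, ...) as_tibble(x)

#' @export
glance.bloc_set <- function(x, ...) {
  tibble(n_blocs = nrow(x),
         length_threshold = attr(x, "length_threshold"),
         total_span = sum(x$end - x$start),
         median_length = if (nrow(x)) median(x$length) else NA_real_,
         n_genes_inside = if ("n_genes" %in% names(x)) sum(x$n_genes)
                          else NA_integer_)
}

#' @export
tidy.dmr_set <- function(x, ...) as_tibble(x)

#' @export
glance.dmr_set <- function(x, ...) {
  ct <- attr(x, "cell_types")
  tibble(n_sites = nrow(x),
         n_dmrs = sum(x$direction != "none"),
         !!paste0("n_", ct[1], "_hyper") :=
           sum(x$direction == paste0(ct[1], "-hyper")),
         !!paste0("n_", ct[2], "_hyper") :=
           sum(x$direction == paste0(ct[2], "-hyper")),
         p_cutoff = attr(x, "p_cutoff"))
}

#' @export
tidy.pattern_table <- function(x, ...) as_tibble(x)

#' @export
glance.pattern_table <- function(x, ...) {
  tibble(n_patterns = nrow(x),
         n_genes = sum(x$n_genes),
         n_excluded = attr(x, "n_excluded"),
         n_categorized = sum(x$n_genes[!is.na(x$category)]))
}

#' @export
tidy.enrichment_scan <- function(x, ...) as_tibble(x)

#' @export
glance.enrichment_scan <- function(x, ...) {
  tibble(n_patterns = nrow(x),
         n_testable = sum(x$testable),
         n_significant = sum(x$testable & x$p_value < 0.05, na.rm = TRUE),
         min_p = suppressWarnings(min(x$p_value, na.rm = TRUE)))
}
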