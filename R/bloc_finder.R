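#' Detect broad repressive domains (blocs)
#'
#' A bloc is an enriched island — called at the domain-scale preset
#' ([bloc_params()], 10 kb windows) — whose span meets or exceeds a length
#' threshold (default 100 kb). Islands below the threshold are discarded;
#' islands are not merged beyond the caller's own gap rule.
#'
#' @param islands An `island_set` from [find_islands()] (10 kb window preset).
#' @param length_threshold Minimum span in bp (default 1e5).
#' @param genes Optional gene tibble; when given, genes whose TSS lies inside
#'   a bloc are listed.
#' @return Tibble of class `bloc_set`: `chrom`, `start`, `end`, `length`,
#'   `n_windows`, and (when `genes` given) `genes_inside` (comma-separated
#'   gene ids) and `n_genes`.
#' @export
find_blocs <- function(islands, length_threshold = 1e5, genes = NULL) {
  stopifnot(length_threshold > 0)
  blocs <- islands %>%
    as_tibble() %>%
    mutate(length = .data$end - .data$start) %>%
    filter(.data$length >= length_threshold) %>%
    select("chrom", "start", "end", "length", "n_windows") %>%
    arrange(.data$chrom, .data$start)
  if (!is.null(genes)) {
    blocs$genes_inside <- ""
    blocs$n_genes <- 0L
    if (nrow(blocs) > 0 && nrow(genes) > 0) {
      tsspts <- tibble(chrom = genes$chrom, start = genes$tss,
                       end = genes$tss + 1L)
      hits <- overlap_pairs(tsspts, blocs)
      if (nrow(hits) > 0) {
        agg <- hits %>%
          group_by(.data$b_idx) %>%
          summarise(ids = paste(genes$gene_id[.data$a_idx], collapse = ","),
                    n = n(), .groups = "drop")
        blocs$genes_inside[agg$b_idx] <- agg$ids
        blocs$n_genes[agg$b_idx] <- agg$n
      }
    }
  }
  structure(blocs, class = c("bloc_set", class(tibble())),
            length_threshold = length_threshold)
}

#' Fraction of each expression class located inside blocs
#'
#' For each expression class, the fraction of genes whose TSS lies within a
#' bloc. A gene belongs to a bloc by the TSS-in-bloc rule.
#'
#' @param blocs A `bloc_set` (or interval tibble) for one cell type.
#' @param genes Gene tibble with `tss`.
#' @param expr_classes Tibble `gene_id`, `expr_class`.
#' @return Tibble `expr_class`, `n_genes`, `n_in_bloc`, `fraction`. Classes
#'   with no genes are absent (fraction undefined, not 0).
#' @export
bloc_gene_fractions <- function(blocs, genes, expr_classes) {
  stopifnot(all(c("gene_id", "expr_class") %in% names(expr_classes)))
  genes <- inner_join(genes, expr_classes, by = "gene_id")
  in_bloc <- rep(FALSE, nrow(genes))
  if (nrow(blocs) > 0 && nrow(genes) > 0) {
    tsspts <- tibble(chrom = genes$chrom, start = genes$tss,
                     end = genes$tss + 1L)
    hits <- overlap_pairs(tsspts, as_tibble(blocs))
    in_bloc[unique(hits$a_idx)] <- TRUE
  }
  genes %>%
    mutate(in_bloc = in_bloc) %>%
    group_by(.data$expr_class) %>%
    summarise(n_genes = n(), n_in_bloc = sum(.data$in_bloc),
              fraction = .data$n_in_bloc / .data$n_genes, .groups = "drop")
}
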