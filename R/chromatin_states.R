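#' Promoter mark calls for a set of genes
#'
#' A gene carries a mark if its promoter window (TSS +/- `flank` bp) overlaps
#' at least one enriched island by at least 1 bp (half-open coordinates: an
#' island ending exactly where the promoter starts does not overlap).
#'
#' @param genes Gene tibble.
#' @param islands Island interval tibble (one cell type, one mark).
#' @param flank Promoter half-width in bp (default 5000).
#' @return Logical vector, one element per row of `genes`.
#' @export
promoter_mark_calls <- function(genes, islands, flank = 5000) {
  out <- rep(FALSE, nrow(genes))
  if (nrow(genes) == 0 || is.null(islands) || nrow(islands) == 0) return(out)
  prom <- promoter_windows(genes, flank)
  hits <- overlap_pairs(prom, as_tibble(islands))
  out[unique(hits$a_idx)] <- TRUE
  out
}

state_levels <- c("bivalent", "K4-only", "K27-only", "neither")

state_from_marks <- function(k4, k27) {
  factor(case_when(k4 & k27 ~ "bivalent",
                   k4 & !k27 ~ "K4-only",
                   !k4 & k27 ~ "K27-only",
                   TRUE ~ "neither"),
         levels = state_levels)
}

#' Classify genes into four chromatin states per cell type
#'
#' Each gene, in each cell type, is assigned one of four promoter chromatin
#' states from its K4 and K27 island overlap: `bivalent` (both marks),
#' `K4-only`, `K27-only`, or `neither`. The partition is exhaustive and
#' exclusive.
#'
#' @param genes Gene tibble.
#' @param islands Tibble of enriched islands across libraries with columns
#'   `cell_type`, `mark` (`"K4"`/`"K27"`), `chrom`, `start`, `end`.
#' @param cell_types Cell types to classify (default: those in `islands`).
#' @param flank Promoter half-width in bp.
#' @return Tibble `gene_id`, `cell_type`, `k4`, `k27`, `state`.
#' @export
classify_states <- function(genes, islands, cell_types = NULL, flank = 5000) {
  if (is.null(cell_types)) cell_types <- unique(islands$cell_type)
  purrr::map_dfr(cell_types, function(ct) {
    k4 <- promoter_mark_calls(
      genes, filter(islands, .data$cell_type == ct, .data$mark == "K4"), flank)
    k27 <- promoter_mark_calls(
      genes, filter(islands, .data$cell_type == ct, .data$mark == "K27"), flank)
    tibble(gene_id = genes$gene_id, cell_type = ct, k4 = k4, k27 = k27,
           state = state_from_marks(k4, k27))
  })
}

# The seven named transition patterns (states in hES, CD44, CD24 order).
transition_categories <- function() {
  tibble(
    category = 1:7,
    hES = "bivalent",
    s2 = c("K4-only", "K4-only", "K4-only", "bivalent", "K27-only",
           "bivalent", "K27-only"),
    s3 = c("K4-only", "bivalent", "K27-only", "K4-only", "K4-only",
           "bivalent", "K27-only")
  )
}

#' Cross-cell-type chromatin pattern table
#'
#' Tabulates gene counts over all 64 ordered combinations of the four
#' chromatin states across three cell types, and labels the seven named
#' bivalency-resolution categories (all start bivalent in hES):
#' 1 Biv-K4-K4, 2 Biv-K4-Biv, 3 Biv-K4-K27, 4 Biv-Biv-K4, 5 Biv-K27-K4,
#' 6 Biv-Biv-Biv, 7 Biv-K27-K27.
#'
#' @param states Output of [classify_states()] covering three cell types.
#' @param cell_types Ordered character vector of the three cell types
#'   (reference first; default `c("hES", "CD44", "CD24")`).
#' @return Tibble of 64 rows: one state column per cell type, `n_genes`,
#'   `category` (integer 1-7 or `NA`). Genes missing a state in any cell type
#'   are excluded (their count is reported in attribute `n_excluded`).
#' @export
pattern_table <- function(states, cell_types = c("hES", "CD44", "CD24")) {
  stopifnot(length(cell_types) == 3)
  wide <- states %>%
    filter(.data$cell_type %in% cell_types) %>%
    select("gene_id", "cell_type", "state") %>%
    tidyr::pivot_wider(names_from = "cell_type", values_from = "state")
  missing_ct <- setdiff(cell_types, names(wide))
  for (ct in missing_ct) wide[[ct]] <- factor(NA, levels = state_levels)
  complete <- stats::complete.cases(wide[cell_types])
  n_excluded <- sum(!complete)
  wide <- wide[complete, ]

  grid <- tidyr::expand_grid(
    s1 = factor(state_levels, levels = state_levels),
    s2 = factor(state_levels, levels = state_levels),
    s3 = factor(state_levels, levels = state_levels))
  names(grid) <- cell_types
  counts <- wide %>% count(across(all_of(cell_types)), name = "n_genes")
  out <- grid %>%
    left_join(counts, by = cell_types) %>%
    mutate(n_genes = tidyr::replace_na(.data$n_genes, 0L))

  cat_key <- transition_categories()
  names(cat_key) <- c("category", cell_types)
  out <- left_join(out, cat_key, by = cell_types)
  structure(out, class = c("pattern_table", class(tibble())),
            n_excluded = n_excluded, cell_types = cell_types)
}

#' Shared, lost, and gained K27 gene sets between two cell types
#'
#' Partitions K27-promoter-marked genes by comparison of a progenitor-like
#' and a differentiated cell type: marked in both (`shared`), marked only in
#' the first (`lost` during commitment), marked only in the second
#' (`gained`).
#'
#' @param states Output of [classify_states()].
#' @param from,to The two cell types compared (default `"CD44"` to `"CD24"`).
#' @return Named list of character vectors `shared`, `lost`, `gained`.
#' @export
count_k27_gene_sets <- function(states, from = "CD44", to = "CD24") {
  k27_genes <- function(ct) {
    states %>% filter(.data$cell_type == ct, .data$k27) %>% pull("gene_id")
  }
  a <- k27_genes(from)
  b <- k27_genes(to)
  list(shared = intersect(a, b), lost = setdiff(a, b), gained = setdiff(b, a))
}

#' Per-gene promoter tag counts and cross-library correlation
#'
#' Counts tag 5' positions within TSS +/- `flank` bp per gene for two
#' libraries and reports their Pearson correlation (raw counts by default).
#'
#' @param lib_a,lib_b Two [tag_library()] objects on the same genome.
#' @param genes Gene tibble (>= 2 genes).
#' @param flank Promoter half-width in bp.
#' @param log Correlate log2(count + 1) instead of raw counts?
#' @return List with `counts` (tibble `gene_id`, `count_a`, `count_b`) and
#'   `correlation`.
#' @export
promoter_tag_count_correlation <- function(lib_a, lib_b, genes, flank = 5000,
                                           log = FALSE) {
  if (nrow(genes) < 2) abort("need at least 2 genes for a correlation")
  prom <- promoter_windows(genes, flank)
  counts <- tibble(gene_id = genes$gene_id,
                   count_a = count_tags_in(lib_a, prom),
                   count_b = count_tags_in(lib_b, prom))
  x <- counts$count_a
  y <- counts$count_b
  if (log) {
    x <- log2(x + 1)
    y <- log2(y + 1)
  }
  list(counts = counts, correlation = cor(x, y, method = "pearson"))
}
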