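#' Normalize tag counts to tags per 10 million
#'
#' @param counts Long tibble `gene_id`, `library_id`, `cell_type`, `count`.
#' @param totals Optional named vector of library totals (names =
#'   `library_id`); by default the per-library sum of `count`.
#' @param target Scaling target (default 1e7).
#' @return The input with a `norm` column (count x target / library total).
#' @export
normalize_counts <- function(counts, totals = NULL, target = 1e7) {
  stopifnot(all(c("gene_id", "library_id", "count") %in% names(counts)))
  if (is.null(totals)) {
    tt <- counts %>%
      group_by(.data$library_id) %>%
      summarise(total = sum(.data$count), .groups = "drop")
  } else {
    tt <- tibble(library_id = names(totals), total = unname(totals))
  }
  if (any(tt$total <= 0)) abort("library total must be positive")
  counts %>%
    left_join(tt, by = "library_id") %>%
    mutate(norm = .data$count * target / .data$total) %>%
    select(-"total")
}

#' Classify genes into four expression classes
#'
#' Classifies each gene as `CD44-high`, `CD24-high`, `no-difference`, or
#' `not-expressed` from normalized SAGE tag counts. A gene is
#' `not-expressed` when its maximum normalized count over all libraries is
#' below `expressed_floor`. It is high in one cell type when the
#' pseudocounted fold change meets `min_fold` in at least `consistency` of
#' all cross-replicate library pairs (default: all pairs, the strictest
#' reading of consistent differential expression).
#'
#' @param counts Long tibble with `gene_id`, `library_id`, `cell_type`,
#'   `count` (normalized column `norm` added via [normalize_counts()] if
#'   absent).
#' @param cell_types Length-2 character vector, first vs second
#'   (default `c("CD44", "CD24")`).
#' @param min_fold Fold-change threshold (default 2).
#' @param expressed_floor Minimum normalized count to count as expressed
#'   (default 5 tags per 10 million).
#' @param consistency Fraction of replicate pairs that must satisfy the fold
#'   criterion (default 1 = all).
#' @param pseudocount Added to both sides of every fold ratio (normalized
#'   scale; default 1).
#' @return Tibble `gene_id`, `median_a`, `median_b` (per-cell-type medians of
#'   normalized counts), `fold_change` (pseudocounted a/b), `expr_class`.
#' @export
classify_expression <- function(counts, cell_types = c("CD44", "CD24"),
                                min_fold = 2, expressed_floor = 5,
                                consistency = 1, pseudocount = 1) {
  stopifnot(length(cell_types) == 2)
  if (!"norm" %in% names(counts)) counts <- normalize_counts(counts)
  counts <- filter(counts, .data$cell_type %in% cell_types)

  wide <- counts %>%
    select("gene_id", "library_id", "cell_type", "norm") %>%
    tidyr::pivot_wider(names_from = c("cell_type", "library_id"),
                       values_from = "norm", values_fill = 0)
  libs_a <- grep(paste0("^", cell_types[1], "_"), names(wide))
  libs_b <- grep(paste0("^", cell_types[2], "_"), names(wide))
  if (length(libs_a) == 0 || length(libs_b) == 0) {
    abort("need at least one library per cell type")
  }
  ma <- as.matrix(wide[, libs_a, drop = FALSE])
  mb <- as.matrix(wide[, libs_b, drop = FALSE])

  # all cross-replicate pair ratios, genes x (na * nb)
  frac_ge <- function(num, den) {
    hit <- 0L
    tot <- ncol(num) * ncol(den)
    ok <- matrix(0L, nrow = nrow(num), ncol = 1)
    for (i in seq_len(ncol(num))) {
      for (j in seq_len(ncol(den))) {
        ok <- ok + ((num[, i] + pseudocount) / (den[, j] + pseudocount) >= min_fold)
      }
    }
    as.numeric(ok) / tot
  }
  fa <- frac_ge(ma, mb)
  fb <- frac_ge(mb, ma)
  max_norm <- pmax(apply(ma, 1, max), apply(mb, 1, max))
  med_a <- apply(ma, 1, median)
  med_b <- apply(mb, 1, median)

  tibble(
    gene_id = wide$gene_id,
    median_a = med_a,
    median_b = med_b,
    fold_change = (med_a + pseudocount) / (med_b + pseudocount),
    expr_class = case_when(
      max_norm < expressed_floor ~ "not-expressed",
      fa >= consistency ~ paste0(cell_types[1], "-high"),
      fb >= consistency ~ paste0(cell_types[2], "-high"),
      TRUE ~ "no-difference")
  )
}

#' Rank-sum comparison of expression between two gene sets
#'
#' Two-sided Wilcoxon rank-sum test on a chosen expression column between two
#' gene sets.
#'
#' @param expr Expression tibble keyed by `gene_id` (e.g. the output of
#'   [classify_expression()]).
#' @param set_a,set_b Character vectors of gene ids (each of size >= 2).
#' @param value Name of the numeric column to compare (default `"median_a"`).
#' @return Tibble `n_a`, `n_b`, `statistic`, `p_value`.
#' @export
compare_group_expression <- function(expr, set_a, set_b, value = "median_a") {
  xa <- expr[[value]][expr$gene_id %in% set_a]
  xb <- expr[[value]][expr$gene_id %in% set_b]
  if (length(xa) < 2 || length(xb) < 2) {
    abort("each gene set must contribute at least 2 genes")
  }
  wt <- suppressWarnings(wilcox.test(xa, xb, alternative = "two.sided"))
  tibble(n_a = length(xa), n_b = length(xb),
         statistic = unname(wt$statistic), p_value = wt$p.value)
}
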