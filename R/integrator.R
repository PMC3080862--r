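#' Histone-mark presence near DMRs
#'
#' For each DMR, tests whether the site flanked by a mark-specific margin
#' overlaps an enriched island in each cell type: +/- 5 kb for the broad K27
#' mark, +/- 0 bp (the site itself) for the punctate K4 mark.
#'
#' @param dmrs Tibble with `site_id`, `chrom`, `pos`.
#' @param islands Tibble of islands with `cell_type`, `mark`, `chrom`,
#'   `start`, `end`.
#' @param k27_flank,k4_flank Flanks in bp (defaults 5000 and 0).
#' @return Long tibble `site_id`, `cell_type`, `mark`, `present`.
#' @export
marks_near_dmrs <- function(dmrs, islands, k27_flank = 5000, k4_flank = 0) {
  combos <- distinct(islands, .data$cell_type, .data$mark)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    ct <- combos$cell_type[i]
    mk <- combos$mark[i]
    flank <- if (mk == "K27") k27_flank else k4_flank
    isl <- filter(islands, .data$cell_type == ct, .data$mark == mk)
    win <- tibble(chrom = dmrs$chrom,
                  start = pmax(0, dmrs$pos - flank),
                  end = dmrs$pos + flank + 1L)
    present <- rep(FALSE, nrow(dmrs))
    if (nrow(isl) > 0 && nrow(dmrs) > 0) {
      hits <- overlap_pairs(win, isl)
      present[unique(hits$a_idx)] <- TRUE
    }
    tibble(site_id = dmrs$site_id, cell_type = ct, mark = mk,
           present = present)
  })
}

#' Assemble the per-gene integration table
#'
#' Full outer join of the chromatin, expression, and methylation layers by
#' `gene_id`. Genes absent from a layer carry `NA` (chromatin/expression) or
#' `"none"` (DMR columns, meaning no significant DMR linked).
#'
#' @param genes Gene tibble (defines the record universe).
#' @param states [classify_states()] output.
#' @param expr [classify_expression()] output.
#' @param dmr_links [link_dmrs_to_genes()] output for significant DMRs joined
#'   with `direction`.
#' @param all_links The same for all sites; used to flag which genes have any
#'   restriction site in each region class (`has_promoter_site`,
#'   `has_genebody_site`), the background universe for enrichment tests.
#' @return Tibble of class `gene_state_table`: `gene_id`, `expr_class`,
#'   `k4_<ct>`/`k27_<ct>` per cell type, `promoter_dmr`, `genebody_dmr`,
#'   `has_promoter_site`, `has_genebody_site`.
#' @export
assemble_gene_state <- function(genes, states, expr, dmr_links, all_links) {
  if (anyDuplicated(expr$gene_id)) abort("duplicate gene_id in expression layer")
  st_wide <- states %>%
    select("gene_id", "cell_type", "k4", "k27") %>%
    tidyr::pivot_wider(names_from = "cell_type", values_from = c("k4", "k27"))
  if (anyDuplicated(st_wide$gene_id)) abort("duplicate gene_id in state layer")

  dmr_region <- function(links, reg, col) {
    links %>%
      filter(.data$region == reg, .data$direction != "none") %>%
      group_by(.data$gene_id) %>%
      summarise(!!col := paste(sort(unique(.data$direction)), collapse = ";"),
                .groups = "drop")
  }
  prom <- dmr_region(dmr_links, "promoter", "promoter_dmr")
  body <- dmr_region(dmr_links, "gene_body", "genebody_dmr")
  site_flags <- tibble(gene_id = genes$gene_id) %>%
    mutate(
      has_promoter_site = .data$gene_id %in%
        all_links$gene_id[all_links$region == "promoter"],
      has_genebody_site = .data$gene_id %in%
        all_links$gene_id[all_links$region == "gene_body"])

  out <- tibble(gene_id = genes$gene_id) %>%
    left_join(select(expr, "gene_id", "expr_class"), by = "gene_id") %>%
    left_join(st_wide, by = "gene_id") %>%
    left_join(prom, by = "gene_id") %>%
    left_join(body, by = "gene_id") %>%
    left_join(site_flags, by = "gene_id") %>%
    mutate(promoter_dmr = tidyr::replace_na(.data$promoter_dmr, "none"),
           genebody_dmr = tidyr::replace_na(.data$genebody_dmr, "none"))
  structure(out, class = c("gene_state_table", class(tibble())))
}

#' Enrichment of a joint pattern among DMR-bearing genes
#'
#' Builds the 2x2 table (pattern vs not) x (DMR vs not) over a background
#' universe and tests association with Fisher's exact test (two-sided).
#' `pattern` and `dmr` are tidy-evaluated logical expressions on the columns
#' of `records`; `universe` restricts the background (e.g. genes with at
#' least one restriction site in the tested region class).
#'
#' @param records A `gene_state_table` (or any tibble).
#' @param pattern,dmr Logical expressions (unquoted) defining the two
#'   classifications.
#' @param universe Optional logical expression restricting the background.
#' @param label Optional descriptor carried into the result.
#' @return One-row tibble of class `enrichment_result`: `label`, `observed`,
#'   `expected`, `oe_ratio`, `p_value`, `n_universe`, `testable`. Degenerate
#'   tables (an empty margin) are flagged `testable = FALSE` with `NA`
#'   p-value.
#' @export
pattern_enrichment <- function(records, pattern, dmr, universe = NULL,
                               label = NA_character_) {
  pat_q <- enquo(pattern)
  dmr_q <- enquo(dmr)
  uni_q <- enquo(universe)
  df <- as_tibble(records)
  if (!rlang::quo_is_null(uni_q)) {
    keep <- eval_tidy(uni_q, df)
    keep[is.na(keep)] <- FALSE
    df <- df[keep, , drop = FALSE]
  }
  p <- eval_tidy(pat_q, df)
  d <- eval_tidy(dmr_q, df)
  p[is.na(p)] <- FALSE
  d[is.na(d)] <- FALSE
  enrichment_from_flags(p, d, label)
}

# Core 2x2 construction shared by pattern_enrichment and scans.
enrichment_from_flags <- function(p, d, label = NA_character_) {
  tab <- matrix(c(sum(p & d), sum(p & !d), sum(!p & d), sum(!p & !d)),
                nrow = 2)
  n <- sum(tab)
  observed <- tab[1, 1]
  expected <- if (n > 0) sum(tab[1, ]) * sum(tab[, 1]) / n else NA_real_
  testable <- n > 0 && all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  pv <- if (testable) fisher.test(tab)$p.value else NA_real_
  out <- tibble(label = label, observed = observed, expected = expected,
                oe_ratio = ifelse(!is.na(expected) & expected > 0,
                                  observed / expected, NA_real_),
                p_value = pv, n_universe = n, testable = testable)
  structure(out, class = c("enrichment_result", class(tibble())))
}

#' Scan a family of joint methylation x chromatin x expression patterns
#'
#' Runs [pattern_enrichment()] for every combination of DMR region
#' (promoter / gene body), DMR direction, expression class, and K27 status in
#' each cell type, over the region-matched site-bearing background. Raw
#' Fisher p-values are reported alongside BH-adjusted values across the
#' family.
#'
#' @param records A `gene_state_table` from [assemble_gene_state()].
#' @param cell_types Cell types whose K27 columns are scanned (default
#'   `c("CD44", "CD24")`).
#' @param expr_classes Expression classes scanned (default the two `-high`
#'   classes of `cell_types`).
#' @return Tibble: `region`, `dmr_direction`, `expr_class`, `k27_cell_type`,
#'   `observed`, `expected`, `oe_ratio`, `p_value`, `q_value`, `testable`.
#' @export
enrichment_scan <- function(records, cell_types = c("CD44", "CD24"),
                            expr_classes = paste0(cell_types, "-high")) {
  dirs <- paste0(cell_types, "-hyper")
  grid <- tidyr::expand_grid(
    region = c("promoter", "gene_body"),
    dmr_direction = dirs,
    expr_class = expr_classes,
    k27_cell_type = cell_types)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    dmr_col <- if (g$region == "promoter") "promoter_dmr" else "genebody_dmr"
    uni_col <- if (g$region == "promoter") "has_promoter_site" else "has_genebody_site"
    df <- records[records[[uni_col]] %in% TRUE, , drop = FALSE]
    pat <- df$expr_class %in% g$expr_class &
      df[[paste0("k27_", g$k27_cell_type)]] %in% TRUE
    dm <- vapply(strsplit(df[[dmr_col]], ";", fixed = TRUE),
                 function(v) g$dmr_direction %in% v, logical(1))
    enrichment_from_flags(pat, dm)[, -1]
  })
  out <- dplyr::bind_cols(grid, res) %>%
    mutate(q_value = p.adjust(.data$p_value, method = "BH"))
  structure(out, class = c("enrichment_scan", class(tibble())))
}
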