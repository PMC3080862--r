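#' Exact conditional test for a difference in two Poisson rates
#'
#' Tests whether two tag counts arising from Poisson sampling at library
#' depths `n_a` and `n_b` share a common per-tag rate. Conditional on the
#' total `x_a + x_b = n`, `x_a` is Binomial(n, n_a / (n_a + n_b)) under the
#' null; the two-sided p-value sums the probabilities of all outcomes no more
#' likely than the observed one (minimum-likelihood convention). With
#' `n = 0` the test is uninformative and returns 1.
#'
#' @param x_a,x_b Observed tag counts (vectorized).
#' @param n_a,n_b Library totals (> 0).
#' @return Two-sided p-value(s) in (0, 1].
#' @export
dmr_test <- function(x_a, n_a, x_b, n_b) {
  stopifnot(all(n_a > 0), all(n_b > 0), all(x_a >= 0), all(x_b >= 0))
  m <- max(length(x_a), length(x_b), length(n_a), length(n_b))
  x_a <- rep_len(x_a, m); x_b <- rep_len(x_b, m)
  n_a <- rep_len(n_a, m); n_b <- rep_len(n_b, m)
  vapply(seq_len(m), function(i) {
    n <- x_a[i] + x_b[i]
    if (n == 0) return(1)
    p0 <- n_a[i] / (n_a[i] + n_b[i])
    probs <- dbinom(0:n, n, p0)
    # relative tolerance guards against ties lost to floating error
    min(1, sum(probs[probs <= probs[x_a[i] + 1] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Call differentially methylated sites (DMRs)
#'
#' Pools replicate libraries per cell type (counts and totals summed), tests
#' each restriction site with [dmr_test()], and labels significant sites by
#' direction. Because the enzyme cuts only unmethylated sites, fewer
#' normalized tags means more methylation: a site with a lower normalized
#' count in a cell type is hypermethylated in that cell type.
#'
#' @param site_counts Long tibble `site_id`, `chrom`, `pos`, `library_id`,
#'   `cell_type`, `count`.
#' @param p_cutoff Significance threshold (default 0.01).
#' @param cell_types Length-2 vector (default `c("CD44", "CD24")`).
#' @param totals Optional named vector of library totals; by default each
#'   library's sum of counts.
#' @return Tibble of class `dmr_set`, one row per site: `site_id`, `chrom`,
#'   `pos`, `x_a`, `x_b`, `n_a`, `n_b`, `p_value`, `direction` (one of
#'   `"<cell_types[1]>-hyper"`, `"<cell_types[2]>-hyper"`, `"none"`).
#' @export
call_dmrs <- function(site_counts, p_cutoff = 0.01,
                      cell_types = c("CD44", "CD24"), totals = NULL) {
  stopifnot(length(cell_types) == 2, p_cutoff > 0, p_cutoff < 1)
  sc <- filter(site_counts, .data$cell_type %in% cell_types)
  if (is.null(totals)) {
    tt <- sc %>%
      group_by(.data$library_id) %>%
      summarise(total = sum(.data$count), .groups = "drop")
  } else {
    tt <- tibble(library_id = names(totals), total = unname(totals))
  }
  lib_ct <- distinct(sc, .data$library_id, .data$cell_type) %>%
    left_join(tt, by = "library_id")
  nn <- lib_ct %>%
    group_by(.data$cell_type) %>%
    summarise(n = sum(.data$total), .groups = "drop")
  n_a <- nn$n[nn$cell_type == cell_types[1]]
  n_b <- nn$n[nn$cell_type == cell_types[2]]
  if (length(n_a) == 0 || length(n_b) == 0) {
    abort("need at least one library per cell type")
  }

  pooled <- sc %>%
    group_by(.data$site_id, .data$chrom, .data$pos, .data$cell_type) %>%
    summarise(x = sum(.data$count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "cell_type", values_from = "x",
                       values_fill = 0L)
  x_a <- pooled[[cell_types[1]]]
  x_b <- pooled[[cell_types[2]]]
  p <- dmr_test(x_a, n_a, x_b, n_b)
  rate_a <- x_a / n_a
  rate_b <- x_b / n_b
  direction <- case_when(
    p >= p_cutoff | rate_a == rate_b ~ "none",
    rate_a < rate_b ~ paste0(cell_types[1], "-hyper"),
    TRUE ~ paste0(cell_types[2], "-hyper"))

  out <- tibble(site_id = pooled$site_id, chrom = pooled$chrom,
                pos = pooled$pos, x_a = x_a, x_b = x_b,
                n_a = n_a, n_b = n_b, p_value = p, direction = direction) %>%
    arrange(.data$chrom, .data$pos)
  structure(out, class = c("dmr_set", class(tibble())),
            p_cutoff = p_cutoff, cell_types = cell_types)
}

#' Link restriction sites to genes by TSS-relative position
#'
#' Pairs every site with every gene whose TSS lies within `max_dist` bp, with
#' strand-aware signed distance (positive downstream of the TSS in the gene's
#' direction of transcription). Region labels: `promoter` for distances in
#' [-promoter_up, body_start), `gene_body` for [body_start, gene length),
#' `neither` otherwise.
#'
#' @param sites Tibble with `site_id`, `chrom`, `pos` (e.g. a `dmr_set`).
#' @param genes Gene tibble.
#' @param max_dist Link radius around the TSS in bp (default 150,000).
#' @param promoter_up Upstream promoter extent in bp (default 5000).
#' @param body_start Distance at which the gene body begins (default 2000).
#' @return Tibble `site_id`, `gene_id`, `distance`, `region`.
#' @export
link_dmrs_to_genes <- function(sites, genes, max_dist = 150000,
                               promoter_up = 5000, body_start = 2000) {
  if (nrow(sites) == 0 || nrow(genes) == 0) {
    return(tibble(site_id = character(), gene_id = character(),
                  distance = integer(), region = character()))
  }
  windows <- genes %>%
    mutate(start = pmax(0, .data$tss - max_dist),
           end = .data$tss + max_dist + 1L) %>%
    select("chrom", "start", "end")
  pts <- tibble(chrom = sites$chrom, start = sites$pos,
                end = sites$pos + 1L)
  hits <- overlap_pairs(pts, windows)
  if (nrow(hits) == 0) {
    return(tibble(site_id = character(), gene_id = character(),
                  distance = integer(), region = character()))
  }
  g <- genes[hits$b_idx, ]
  s <- sites[hits$a_idx, ]
  dist <- ifelse(g$strand == "+", s$pos - g$tss, g$tss - s$pos)
  glen <- g$end - g$start
  tibble(
    site_id = s$site_id,
    gene_id = g$gene_id,
    distance = as.integer(dist),
    region = case_when(
      dist >= -promoter_up & dist < body_start ~ "promoter",
      dist >= body_start & dist < glen ~ "gene_body",
      TRUE ~ "neither")
  )
}

#' Expression-class composition around DMRs by TSS-relative position
#'
#' Bins site-gene links by signed TSS distance and reports, per bin and DMR
#' direction, the distribution of linked genes over the expression classes
#' (fractions within a bin sum to 1). Apply to unfiltered links (all sites)
#' for the background control profile.
#'
#' @param links Output of [link_dmrs_to_genes()], joined with a `direction`
#'   column (from the `dmr_set`); for a control profile pass all sites with
#'   `direction = "all"`.
#' @param expr_classes Tibble `gene_id`, `expr_class`.
#' @param bin_width Bin width in bp (default 5000).
#' @param max_dist Profile half-range in bp (default 150,000).
#' @return Tibble of class `position_profile`: `direction`, `bin_mid`,
#'   `expr_class`, `n`, `fraction`.
#' @export
positional_association_profile <- function(links, expr_classes,
                                           bin_width = 5000,
                                           max_dist = 150000) {
  stopifnot("direction" %in% names(links))
  breaks <- seq(-max_dist, max_dist, by = bin_width)
  out <- links %>%
    filter(.data$distance >= -max_dist, .data$distance < max_dist) %>%
    inner_join(expr_classes, by = "gene_id") %>%
    mutate(bin_mid = (floor((.data$distance + max_dist) / bin_width) + 0.5) *
             bin_width - max_dist) %>%
    count(.data$direction, .data$bin_mid, .data$expr_class, name = "n") %>%
    group_by(.data$direction, .data$bin_mid) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
  structure(out, class = c("position_profile", class(tibble())),
            bin_width = bin_width, max_dist = max_dist)
}

#' Mean expression of DMR-linked genes vs the all-sites background
#'
#' For each (region, direction) group of DMR-linked genes, reports the mean
#' of an expression column and a two-sided rank-sum test against genes linked
#' to any restriction site in the same region class (the background that
#' controls for site presence). Groups of fewer than 2 genes omit the test.
#'
#' @param dmr_links [link_dmrs_to_genes()] output for significant DMRs,
#'   joined with `direction`; rows with region `"neither"` are ignored.
#' @param all_links The same for all sites (unfiltered).
#' @param expr Expression tibble keyed by `gene_id`.
#' @param value Expression column to compare (default `"median_a"`).
#' @return Tibble `region`, `direction`, `n_genes`, `mean_expr`,
#'   `background_mean`, `p_value`.
#' @export
mean_expression_by_dmr_group <- function(dmr_links, all_links, expr,
                                         value = "median_a") {
  stopifnot("direction" %in% names(dmr_links))
  get_vals <- function(links, reg) {
    ids <- unique(links$gene_id[links$region == reg])
    expr[[value]][expr$gene_id %in% ids]
  }
  groups <- dmr_links %>%
    filter(.data$region %in% c("promoter", "gene_body")) %>%
    distinct(.data$region, .data$direction)
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    reg <- groups$region[i]
    dir <- groups$direction[i]
    ids <- unique(dmr_links$gene_id[dmr_links$region == reg &
                                      dmr_links$direction == dir])
    vals <- expr[[value]][expr$gene_id %in% ids]
    bg <- get_vals(all_links, reg)
    p <- if (length(vals) >= 2 && length(bg) >= 2) {
      suppressWarnings(wilcox.test(vals, bg)$p.value)
    } else {
      NA_real_
    }
    tibble(region = reg, direction = dir, n_genes = length(vals),
           mean_expr = mean(vals), background_mean = mean(bg), p_value = p)
  })
}
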