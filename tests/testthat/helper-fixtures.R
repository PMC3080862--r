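# Shared fixtures. Heavy objects (simulated dataset, called islands) are
# built once per test run and cached.

toy_genome <- function() {
  tibble::tibble(chrom = c("chr1", "chr2"), length = c(1e7, 1e7))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Default coupled dataset (seed 1) and its called layers.
default_fixture <- function() {
  cached("default", {
    cfg <- default_simulation_config(seed = 1)
    ds <- simulate_dataset(cfg)
    islands <- purrr::map_dfr(c("CD44", "CD24", "hES"), function(ct) {
      purrr::map_dfr(c("K4", "K27"), function(mk) {
        isl <- find_islands(ds$chip[[paste0(ct, "_", mk)]],
                            ds$chip[[paste0(ct, "_input")]],
                            cfg$genome, island_params())
        dplyr::mutate(tibble::as_tibble(isl), cell_type = ct, mark = mk)
      })
    })
    states <- classify_states(cfg$genes, islands, c("hES", "CD44", "CD24"))
    expr <- classify_expression(normalize_counts(ds$sage))
    dmrs <- call_dmrs(ds$msdk)
    all_links <- dplyr::left_join(
      link_dmrs_to_genes(dmrs, cfg$genes),
      dplyr::select(tibble::as_tibble(dmrs), site_id, direction),
      by = "site_id")
    list(cfg = cfg, ds = ds, islands = islands, states = states,
         expr = expr, dmrs = dmrs, all_links = all_links,
         dmr_links = dplyr::filter(all_links, direction != "none"))
  })
}

# Hand-built gene table on a single chromosome.
tiny_genes <- function() {
  make_gene_table(tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    start = c(10000L, 100000L, 200000L),
    end = c(30000L, 120000L, 220000L),
    strand = c("+", "-", "+")))
}

write_bed_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
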