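#' Pipeline configuration
#'
#' Collects every threshold of the pipeline in one validated object. Defaults
#' are the published values where one exists: island FDR 0.001, bloc span
#' threshold 100 kb, expression fold 2, DMR p < 0.01, promoter -5 kb..+2 kb /
#' gene body +2 kb..end for DMR assignment, DMR mark flanks +/- 5 kb (K27)
#' and +/- 0 bp (K4).
#'
#' @param simulation A [simulation_config()]; by default the desk-scale
#'   [default_simulation_config()] under `seed`.
#' @param seed Master seed (propagated to the simulation when it is built
#'   here).
#' @param island_fdr Island q-value cutoff.
#' @param island_window,island_gap Point-scale island window/gap (bp).
#' @param bloc_length_threshold Minimum bloc span (bp).
#' @param min_fold Expression fold-change threshold.
#' @param expressed_floor Normalized-count floor for "expressed".
#' @param dmr_p DMR p-value cutoff.
#' @param promoter_up,body_start DMR region boundaries relative to TSS (bp).
#' @param link_max_dist DMR-gene link radius (bp).
#' @param k27_flank,k4_flank DMR mark flanks (bp).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, seed = 1L,
                            island_fdr = 0.001, island_window = 200,
                            island_gap = 600,
                            bloc_length_threshold = 1e5,
                            min_fold = 2, expressed_floor = 5,
                            dmr_p = 0.01,
                            promoter_up = 5000, body_start = 2000,
                            link_max_dist = 150000,
                            k27_flank = 5000, k4_flank = 0) {
  if (is.null(simulation)) simulation <- default_simulation_config(seed)
  cfg <- structure(list(
    simulation = simulation, seed = as.integer(seed),
    island_fdr = island_fdr, island_window = island_window,
    island_gap = island_gap,
    bloc_length_threshold = bloc_length_threshold,
    min_fold = min_fold, expressed_floor = expressed_floor,
    dmr_p = dmr_p, promoter_up = promoter_up, body_start = body_start,
    link_max_dist = link_max_dist,
    k27_flank = k27_flank, k4_flank = k4_flank),
    class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!ok(cfg$island_fdr) || cfg$island_fdr <= 0 || cfg$island_fdr >= 1) {
    abort("island_fdr must lie in (0, 1)")
  }
  if (!ok(cfg$dmr_p) || cfg$dmr_p <= 0 || cfg$dmr_p >= 1) {
    abort("dmr_p must lie in (0, 1)")
  }
  if (!ok(cfg$min_fold) || cfg$min_fold < 1) abort("min_fold must be >= 1")
  if (!ok(cfg$bloc_length_threshold) || cfg$bloc_length_threshold <= 0) {
    abort("bloc_length_threshold must be positive")
  }
  if (!ok(cfg$expressed_floor) || cfg$expressed_floor < 0) {
    abort("expressed_floor must be >= 0")
  }
  if (!inherits(cfg$simulation, "simulation_config")) {
    abort("simulation must be a simulation_config")
  }
  invisible(cfg)
}

#' Run the full pipeline on a simulated dataset
#'
#' Simulates the configured dataset, then runs every stage — island calling
#' per (cell type, mark) against the matched input, bloc detection from the
#' 10 kb preset, chromatin-state classification and the 64-pattern table,
#' expression classification, DMR calling and gene linkage, bloc expression
#' fractions, and the joint enrichment scan — writing each stage's result as
#' TSV/BED under `out_dir` together with a `manifest.json` recording every
#' threshold, the seed, and the MD5 checksum of each output. Deterministic:
#' the same configuration yields byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param cell_types Chromatin cell types (default CD44, CD24, hES).
#' @return Invisibly, a list of the in-memory stage results plus
#'   `manifest`.
#' @export
run_all <- function(config, out_dir,
                    cell_types = c("CD44", "CD24", "hES")) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- config$simulation$genome
  genes <- config$simulation$genes
  ds <- simulate_dataset(config$simulation, cell_types)

  out <- function(...) file.path(out_dir, ...)
  ip <- island_params(window_size = config$island_window,
                      gap_size = config$island_gap,
                      fdr_cutoff = config$island_fdr)

  islands <- purrr::map_dfr(cell_types, function(ct) {
    purrr::map_dfr(c("K4", "K27"), function(mk) {
      isl <- find_islands(ds$chip[[paste(ct, mk, sep = "_")]],
                          ds$chip[[paste(ct, "input", sep = "_")]],
                          genome, ip)
      mutate(as_tibble(isl), cell_type = ct, mark = mk)
    })
  })
  readr::write_tsv(islands, out("islands.tsv"))

  bloc_islands <- purrr::map(setNames(c("CD44", "CD24"), c("CD44", "CD24")),
                             function(ct) {
    find_islands(ds$chip[[paste(ct, "K27", sep = "_")]],
                 ds$chip[[paste(ct, "input", sep = "_")]],
                 genome, bloc_params(fdr_cutoff = config$island_fdr))
  })
  blocs <- purrr::imap_dfr(bloc_islands, function(isl, ct) {
    b <- find_blocs(isl, config$bloc_length_threshold, genes)
    mutate(as_tibble(b), cell_type = ct)
  })
  readr::write_tsv(blocs, out("blocs.tsv"))

  expr <- classify_expression(normalize_counts(ds$sage),
                              min_fold = config$min_fold,
                              expressed_floor = config$expressed_floor)
  readr::write_tsv(expr, out("expression.tsv"))
  expr_classes <- select(expr, "gene_id", "expr_class")

  states <- classify_states(genes, islands, cell_types)
  readr::write_tsv(states, out("states.tsv"))
  patterns <- pattern_table(states, c("hES", "CD44", "CD24"))
  readr::write_tsv(as_tibble(patterns), out("pattern_table.tsv"))

  bloc_fracs <- purrr::map_dfr(c("CD44", "CD24"), function(ct) {
    mutate(bloc_gene_fractions(filter(blocs, .data$cell_type == ct),
                               genes, expr_classes),
           bloc_cell_type = ct)
  })
  readr::write_tsv(bloc_fracs, out("bloc_fractions.tsv"))

  dmrs <- call_dmrs(ds$msdk, p_cutoff = config$dmr_p)
  readr::write_tsv(as_tibble(dmrs), out("dmrs.tsv"))

  all_links <- link_dmrs_to_genes(dmrs, genes,
                                  max_dist = config$link_max_dist,
                                  promoter_up = config$promoter_up,
                                  body_start = config$body_start) %>%
    left_join(select(as_tibble(dmrs), "site_id", "direction"), by = "site_id")
  dmr_links <- filter(all_links, .data$direction != "none")
  readr::write_tsv(dmr_links, out("dmr_gene_links.tsv"))

  profile <- positional_association_profile(
    dmr_links, expr_classes, max_dist = config$link_max_dist)
  readr::write_tsv(as_tibble(profile), out("position_profile.tsv"))

  group_means <- mean_expression_by_dmr_group(
    dmr_links, all_links, expr, value = "median_a")
  readr::write_tsv(group_means, out("dmr_group_expression.tsv"))

  records <- assemble_gene_state(genes, states, expr, dmr_links, all_links)
  readr::write_tsv(records, out("gene_state_table.tsv"))
  enrich <- enrichment_scan(records)
  readr::write_tsv(as_tibble(enrich), out("enrichment.tsv"))

  files <- c("islands.tsv", "blocs.tsv", "expression.tsv", "states.tsv",
             "pattern_table.tsv", "bloc_fractions.tsv", "dmrs.tsv",
             "dmr_gene_links.tsv", "position_profile.tsv",
             "dmr_group_expression.tsv", "gene_state_table.tsv",
             "enrichment.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("epitriad")),
    seed = config$seed,
    thresholds = config[setdiff(names(config), c("simulation", "seed"))],
    checksums = as.list(tools::md5sum(out(files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(islands = islands, blocs = blocs, expr = expr,
                 states = states, patterns = patterns,
                 bloc_fractions = bloc_fracs, dmrs = dmrs,
                 dmr_links = dmr_links, profile = profile,
                 group_means = group_means, records = records,
                 enrichment = enrich, manifest = manifest))
}
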