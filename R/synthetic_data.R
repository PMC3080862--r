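#' Build a simulation configuration
#'
#' Assembles and validates the configuration for the synthetic multi-omic
#' generator: a toy genome, a gene table, a per-gene truth profile (expression
#' class and chromatin state per cell type, planted DMR directions), broad
#' K27 domains, optional free-standing planted islands, restriction-site
#' methylation fractions, and library depths. Every downstream ground-truth
#' label is a deterministic function of this object; randomness enters only
#' when libraries are simulated under `seed`.
#'
#' @param genome Tibble `chrom`, `length`.
#' @param genes Gene tibble (see [make_gene_table()]); may be empty.
#' @param gene_profile Tibble `gene_id`, `expr_class`, `state_hES`,
#'   `state_CD44`, `state_CD24`, `promoter_dmr`, `genebody_dmr`,
#'   `base_abundance`, `de_fold`. May be empty.
#' @param blocs Tibble `cell_type`, `chrom`, `start`, `end`, `fold` of planted
#'   broad K27 domains (spans chosen by the caller; >= 100 kb for true blocs).
#' @param extra_islands Tibble `cell_type`, `mark`, `chrom`, `start`, `end`,
#'   `fold` of free-standing planted enriched regions.
#' @param msdk_sites Tibble `site_id`, `chrom`, `pos`, `meth_CD44`,
#'   `meth_CD24`, `weight`.
#' @param chip_library_size,sage_library_size,msdk_library_size Tags per
#'   simulated library.
#' @param sage_replicates,msdk_replicates Libraries per cell type.
#' @param k4_halfwidth,k27_halfwidth Promoter island half-widths in bp.
#' @param k4_fold,k27_fold,bloc_fold Enrichment folds of planted features.
#' @param background_rate Relative background intensity (tags per bp before
#'   scaling to the library size).
#' @param seed Integer master seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(genome,
                              genes = empty_genes(),
                              gene_profile = empty_profile(),
                              blocs = empty_features(),
                              extra_islands = empty_features(mark = TRUE),
                              msdk_sites = empty_sites(),
                              chip_library_size = 1e5,
                              sage_library_size = 2e5,
                              msdk_library_size = 1e5,
                              sage_replicates = 2,
                              msdk_replicates = 2,
                              k4_halfwidth = 1000,
                              k27_halfwidth = 3000,
                              k4_fold = 8,
                              k27_fold = 6,
                              bloc_fold = 5,
                              background_rate = 1,
                              seed = 1L) {
  check_genome(genome)
  stopifnot(chip_library_size > 0, background_rate > 0,
            k4_fold >= 1, k27_fold >= 1, bloc_fold >= 1)
  in_genome <- function(chrom, start, end) {
    len <- genome$length[match(chrom, genome$chrom)]
    !is.na(len) & start >= 0 & end <= len & end > start
  }
  if (nrow(blocs) > 0 && !all(in_genome(blocs$chrom, blocs$start, blocs$end))) {
    abort("planted bloc outside the genome")
  }
  if (nrow(extra_islands) > 0 &&
      !all(in_genome(extra_islands$chrom, extra_islands$start,
                     extra_islands$end))) {
    abort("planted island outside the genome")
  }
  if (nrow(extra_islands) > 0 && any(extra_islands$fold < 1)) {
    abort("fold_enrichment must be >= 1")
  }
  if (nrow(msdk_sites) > 0) {
    m <- c(msdk_sites$meth_CD44, msdk_sites$meth_CD24)
    if (any(m < 0 | m > 1)) abort("methylation_fraction must lie in [0, 1]")
    if (!all(in_genome(msdk_sites$chrom, msdk_sites$pos, msdk_sites$pos + 1))) {
      abort("restriction site outside the genome")
    }
  }
  structure(list(
    genome = genome, genes = genes, gene_profile = gene_profile,
    blocs = blocs, extra_islands = extra_islands, msdk_sites = msdk_sites,
    chip_library_size = chip_library_size,
    sage_library_size = sage_library_size,
    msdk_library_size = msdk_library_size,
    sage_replicates = sage_replicates, msdk_replicates = msdk_replicates,
    k4_halfwidth = k4_halfwidth, k27_halfwidth = k27_halfwidth,
    k4_fold = k4_fold, k27_fold = k27_fold, bloc_fold = bloc_fold,
    background_rate = background_rate, seed = as.integer(seed)),
    class = "simulation_config")
}

empty_genes <- function() {
  tibble(gene_id = character(), symbol = character(), chrom = character(),
         start = integer(), end = integer(), strand = character(),
         tss = integer())
}
empty_profile <- function() {
  tibble(gene_id = character(), expr_class = character(),
         state_hES = character(), state_CD44 = character(),
         state_CD24 = character(), promoter_dmr = character(),
         genebody_dmr = character(), base_abundance = double(),
         de_fold = double())
}
empty_features <- function(mark = FALSE) {
  out <- tibble(cell_type = character(), chrom = character(),
                start = integer(), end = integer(), fold = double())
  if (mark) out <- tibble::add_column(out, mark = character(), .after = 1)
  out
}
empty_sites <- function() {
  tibble(site_id = character(), chrom = character(), pos = integer(),
         meth_CD44 = double(), meth_CD24 = double(), weight = double())
}

#' Default desk-scale configuration
#'
#' A 2 x 10 Mb toy genome with 300 evenly spaced genes partitioned into
#' truth groups that exercise every downstream stage: reciprocal
#' differentially expressed gene blocks whose promoters swap K4/K27 between
#' cell types (bivalent in the embryonic reference), broad K27 domains
#' (>= 100 kb) over progenitor-specific and silent gene clusters, planted
#' promoter / gene-body DMRs coupled to expression in the repressive and
#' permissive directions, constitutively active, bivalent, and unmarked gene
#' groups, and restriction sites at every promoter and gene body plus an
#' intergenic lattice.
#'
#' @param seed Integer master seed.
#' @return A `simulation_config`.
#' @export
default_simulation_config <- function(seed = 1L) {
  genome <- tibble(chrom = c("chr1", "chr2"), length = c(1e7, 1e7))
  n <- 300L
  idx <- seq_len(n)
  chrom <- ifelse(idx <= 150, "chr1", "chr2")
  local_i <- ifelse(idx <= 150, idx, idx - 150L)
  start <- 30000L + (local_i - 1L) * 66000L
  end <- start + 20000L
  strand <- ifelse(idx %% 2 == 1, "+", "-")
  genes <- make_gene_table(tibble(
    gene_id = sprintf("G%03d", idx), symbol = sprintf("G%03d", idx),
    chrom = chrom, start = start, end = end, strand = strand))

  grp <- function(lo, hi) idx >= lo & idx <= hi
  expr_class <- dplyr::case_when(
    grp(1, 40) ~ "CD44-high",
    grp(41, 80) ~ "CD24-high",
    grp(111, 170) ~ "not-expressed",
    TRUE ~ "no-difference")
  state_CD44 <- dplyr::case_when(
    grp(1, 40) ~ "K4-only",
    grp(41, 80) ~ "K27-only",
    grp(81, 110) | grp(191, 230) ~ "K4-only",
    grp(111, 150) ~ "K27-only",
    grp(171, 190) ~ "bivalent",
    TRUE ~ "neither")
  state_CD24 <- dplyr::case_when(
    grp(1, 40) ~ "K27-only",
    grp(41, 80) ~ "K4-only",
    grp(81, 110) | grp(191, 230) ~ "K4-only",
    grp(111, 150) ~ "K27-only",
    grp(171, 190) ~ "bivalent",
    TRUE ~ "neither")
  state_hES <- dplyr::case_when(
    grp(1, 80) | grp(111, 150) | grp(171, 190) ~ "bivalent",
    grp(81, 110) | grp(191, 230) ~ "K4-only",
    TRUE ~ "neither")
  promoter_dmr <- dplyr::case_when(
    grp(1, 20) ~ "CD24-hyper",
    grp(41, 60) ~ "CD44-hyper",
    TRUE ~ "none")
  genebody_dmr <- dplyr::case_when(
    grp(21, 30) ~ "CD44-hyper",
    grp(61, 70) ~ "CD24-hyper",
    TRUE ~ "none")
  base_abundance <- dplyr::case_when(
    grp(111, 170) ~ 0,
    grp(171, 190) ~ 2,
    grp(1, 80) ~ 5,          # DE genes: low side 5, high side 5 x fold
    TRUE ~ 5 + (idx %% 7) * 2)
  de_fold <- ifelse(grp(1, 80), 4, 1)
  profile <- tibble(gene_id = genes$gene_id[match(sprintf("G%03d", idx),
                                                  genes$gene_id)],
                    expr_class = expr_class, state_hES = state_hES,
                    state_CD44 = state_CD44, state_CD24 = state_CD24,
                    promoter_dmr = promoter_dmr, genebody_dmr = genebody_dmr,
                    base_abundance = base_abundance, de_fold = de_fold)

  # broad K27 domains over consecutive gene runs (gene span +/- 20 kb)
  span_of <- function(lo, hi) {
    g <- dplyr::arrange(genes[genes$gene_id %in% sprintf("G%03d", lo:hi), ],
                        .data$start)
    tibble(chrom = g$chrom[1], start = min(g$start) - 20000L,
           end = max(g$end) + 20000L)
  }
  blocs <- dplyr::bind_rows(
    mutate(span_of(31, 33), cell_type = "CD24"),
    mutate(span_of(36, 38), cell_type = "CD24"),
    mutate(span_of(111, 113), cell_type = "CD24"),
    mutate(span_of(71, 73), cell_type = "CD44"),
    mutate(span_of(120, 122), cell_type = "CD44")) %>%
    mutate(fold = 5) %>%
    select("cell_type", "chrom", "start", "end", "fold")

  # restriction sites: one promoter + one gene-body site per gene, plus an
  # intergenic lattice; methylation follows the planted DMR directions
  meth_of <- function(dmr, ct) {
    dplyr::case_when(dmr == paste0(ct, "-hyper") ~ 0.9,
                     dmr == "none" ~ 0.3,
                     TRUE ~ 0.1)
  }
  dir_sign <- ifelse(genes$strand == "+", 1L, -1L)
  prom_sites <- tibble(
    site_id = paste0("P_", genes$gene_id), chrom = genes$chrom,
    pos = genes$tss + 500L * dir_sign,
    meth_CD44 = meth_of(profile$promoter_dmr, "CD44"),
    meth_CD24 = meth_of(profile$promoter_dmr, "CD24"))
  body_sites <- tibble(
    site_id = paste0("B_", genes$gene_id), chrom = genes$chrom,
    pos = genes$tss + 5000L * dir_sign,
    meth_CD44 = meth_of(profile$genebody_dmr, "CD44"),
    meth_CD24 = meth_of(profile$genebody_dmr, "CD24"))
  k <- seq_len(400L)
  inter_sites <- tibble(
    site_id = sprintf("I_%03d", k),
    chrom = ifelse(k <= 200, "chr1", "chr2"),
    pos = 7000L + ((k - 1L) %% 200L) * 49750L,
    meth_CD44 = 0.3, meth_CD24 = 0.3)
  sites <- dplyr::bind_rows(prom_sites, body_sites, inter_sites) %>%
    mutate(weight = 1 / dplyr::n())

  simulation_config(genome = genome, genes = genes, gene_profile = profile,
                    blocs = blocs, msdk_sites = sites, seed = seed)
}

# Deterministic per-library seed offsets so each library is independently
# reproducible from the master seed.
lib_seed <- function(config, cell_type, assay, rep = 1L) {
  ct <- match(cell_type, c("CD44", "CD24", "hES"))
  as_ <- match(assay, c("K4", "K27", "input", "SAGE", "MSDK"))
  if (is.na(ct) || is.na(as_)) abort("unknown cell_type or assay")
  (config$seed %% 100000L) * 1000L + ct * 100L + as_ * 10L + rep
}

# Planted enrichment features for one (cell type, mark) ChIP library.
chip_features <- function(config, cell_type, mark) {
  feats <- empty_features()
  pr <- config$gene_profile
  if (nrow(pr) > 0 && mark %in% c("K4", "K27")) {
    st <- pr[[paste0("state_", cell_type)]]
    has <- if (mark == "K4") st %in% c("bivalent", "K4-only")
           else st %in% c("bivalent", "K27-only")
    g <- config$genes[match(pr$gene_id[has], config$genes$gene_id), ]
    hw <- if (mark == "K4") config$k4_halfwidth else config$k27_halfwidth
    fold <- if (mark == "K4") config$k4_fold else config$k27_fold
    if (nrow(g) > 0) {
      feats <- bind_rows(feats, tibble(
        cell_type = cell_type, chrom = g$chrom,
        start = pmax(0L, g$tss - as.integer(hw)),
        end = g$tss + as.integer(hw), fold = fold))
    }
  }
  if (mark == "K27" && nrow(config$blocs) > 0) {
    b <- filter(config$blocs, .data$cell_type == !!cell_type)
    feats <- bind_rows(feats, b)
  }
  if (nrow(config$extra_islands) > 0) {
    ei <- filter(config$extra_islands, .data$cell_type == !!cell_type,
                 .data$mark == !!mark)
    feats <- bind_rows(feats, select(ei, -"mark"))
  }
  feats
}

#' Simulate a ChIP (or input) tag library
#'
#' Tag 5' positions are drawn from a piecewise-constant Poisson intensity:
#' the background rate outside planted features and background x fold inside
#' (overlapping features take the maximum fold). Segment weights are scaled
#' so the expected total equals the configured library size. Input libraries
#' (`mark = "input"`) have no planted features.
#'
#' @param config A [simulation_config()].
#' @param cell_type,mark Library identity (`mark` one of `"K4"`, `"K27"`,
#'   `"input"`).
#' @return A [tag_library()].
#' @export
simulate_chip <- function(config, cell_type, mark) {
  check_genome(config$genome)
  set.seed(lib_seed(config, cell_type, mark))
  feats <- if (mark == "input") empty_features() else
    chip_features(config, cell_type, mark)

  segs <- purrr::map_dfr(seq_len(nrow(config$genome)), function(i) {
    chrom <- config$genome$chrom[i]
    len <- config$genome$length[i]
    f <- feats[feats$chrom == chrom, , drop = FALSE]
    bp <- sort(unique(c(0, len, pmin(pmax(c(f$start, f$end), 0), len))))
    s <- head(bp, -1)
    e <- tail(bp, -1)
    fold <- vapply(seq_along(s), function(j) {
      cover <- f$start <= s[j] & f$end >= e[j]
      if (any(cover)) max(f$fold[cover]) else 1
    }, numeric(1))
    tibble(chrom = chrom, start = s, end = e, fold = fold)
  })
  w <- (segs$end - segs$start) * segs$fold * config$background_rate
  scale <- config$chip_library_size / sum(w)
  counts <- rpois(nrow(segs), w * scale)
  pos <- purrr::map2(seq_len(nrow(segs)), counts, function(j, k) {
    if (k == 0) return(integer())
    as.integer(floor(runif(k, segs$start[j], segs$end[j])))
  })
  tags <- tibble(chrom = rep(segs$chrom, counts),
                 start = unlist(pos),
                 end = unlist(pos) + 36L,
                 strand = "*")
  tag_library(tags, library_id = paste(cell_type, mark, sep = "_"),
              cell_type = cell_type, assay = mark)
}

#' Simulate SAGE-seq per-gene tag counts
#'
#' Counts per gene and library are Poisson with mean library size x relative
#' abundance. Differentially expressed genes have their base abundance
#' multiplied by `de_fold` in the high cell type; genes with base abundance 0
#' are never sampled.
#'
#' @param config A [simulation_config()] with a non-empty `gene_profile`.
#' @return Long tibble `gene_id`, `library_id`, `cell_type`, `count`.
#' @export
simulate_sage <- function(config) {
  pr <- config$gene_profile
  if (nrow(pr) == 0) abort("config has no gene_profile")
  abundance_for <- function(ct) {
    high <- pr$expr_class == paste0(ct, "-high")
    pr$base_abundance * ifelse(high, pr$de_fold, 1)
  }
  purrr::map_dfr(c("CD44", "CD24"), function(ct) {
    ab <- abundance_for(ct)
    rel <- if (sum(ab) > 0) ab / sum(ab) else ab
    purrr::map_dfr(seq_len(config$sage_replicates), function(r) {
      set.seed(lib_seed(config, ct, "SAGE", r))
      tibble(gene_id = pr$gene_id,
             library_id = sprintf("%s_SAGE_%d", ct, r),
             cell_type = ct,
             count = rpois(length(rel), config$sage_library_size * rel))
    })
  })
}

#' Simulate MSDK-seq restriction-site tag counts
#'
#' The methylation-sensitive enzyme cuts only unmethylated sites, so the
#' count at site s in a library of cell type t is Poisson with mean
#' library size x weight_s x (1 - methylation fraction of s in t): a fully
#' methylated site yields no tags.
#'
#' @param config A [simulation_config()] with non-empty `msdk_sites`.
#' @return Long tibble `site_id`, `chrom`, `pos`, `library_id`, `cell_type`,
#'   `count`.
#' @export
simulate_msdk <- function(config) {
  ss <- config$msdk_sites
  if (nrow(ss) == 0) abort("config has no msdk_sites")
  purrr::map_dfr(c("CD44", "CD24"), function(ct) {
    meth <- ss[[paste0("meth_", ct)]]
    mu <- config$msdk_library_size * ss$weight * (1 - meth)
    purrr::map_dfr(seq_len(config$msdk_replicates), function(r) {
      set.seed(lib_seed(config, ct, "MSDK", r))
      tibble(site_id = ss$site_id, chrom = ss$chrom, pos = ss$pos,
             library_id = sprintf("%s_MSDK_%d", ct, r),
             cell_type = ct, count = rpois(length(mu), mu))
    })
  })
}

#' Resolve the planted ground truth of a configuration
#'
#' Deterministically (no randomness) maps the configuration to the labels
#' every downstream stage should recover: per-gene chromatin state and mark
#' booleans per cell type, expression class, planted DMR directions per
#' restriction site, planted bloc intervals, and the shared/lost/gained K27
#' gene sets implied by the truth states.
#'
#' @param config A [simulation_config()].
#' @return List `states`, `expr`, `dmr`, `blocs`, `k27_sets`.
#' @export
ground_truth <- function(config) {
  pr <- config$gene_profile
  states <- purrr::map_dfr(c("hES", "CD44", "CD24"), function(ct) {
    st <- pr[[paste0("state_", ct)]]
    tibble(gene_id = pr$gene_id, cell_type = ct,
           k4 = st %in% c("bivalent", "K4-only"),
           k27 = st %in% c("bivalent", "K27-only"),
           state = factor(st, levels = state_levels))
  })
  dmr <- if (nrow(config$msdk_sites) > 0) {
    ss <- config$msdk_sites
    tibble(site_id = ss$site_id,
           direction = case_when(
             ss$meth_CD44 > ss$meth_CD24 ~ "CD44-hyper",
             ss$meth_CD24 > ss$meth_CD44 ~ "CD24-hyper",
             TRUE ~ "none"))
  } else {
    tibble(site_id = character(), direction = character())
  }
  list(states = states,
       expr = select(pr, "gene_id", "expr_class"),
       dmr = dmr,
       blocs = config$blocs,
       k27_sets = count_k27_gene_sets(states))
}

#' Simulate the complete multi-omic dataset
#'
#' @param config A [simulation_config()].
#' @param cell_types Cell types to simulate chromatin for (default all
#'   three).
#' @return List `chip` (named list of [tag_library()]s, names like
#'   `"CD44_K27"`), `sage`, `msdk` (long count tibbles), `truth`
#'   ([ground_truth()]).
#' @export
simulate_dataset <- function(config, cell_types = c("CD44", "CD24", "hES")) {
  marks <- c("K4", "K27", "input")
  chip <- list()
  for (ct in cell_types) {
    for (mk in marks) {
      chip[[paste(ct, mk, sep = "_")]] <- simulate_chip(config, ct, mk)
    }
  }
  list(chip = chip,
       sage = if (nrow(config$gene_profile) > 0) simulate_sage(config) else NULL,
       msdk = if (nrow(config$msdk_sites) > 0) simulate_msdk(config) else NULL,
       truth = ground_truth(config))
}
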