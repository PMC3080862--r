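test_that("promoter mark calls use >= 1 bp overlap with half-open intervals", {
  gene <- make_gene_table(tibble::tibble(
    gene_id = "g", chrom = "chr1", strand = "+",
    start = 10000L, end = 30000L))           # TSS 10000, promoter [5000,15000)
  call1 <- promoter_mark_calls(gene, tibble::tibble(
    chrom = "chr1", start = 9000, end = 12000))
  expect_true(call1)
  call2 <- promoter_mark_calls(gene, tibble::tibble(
    chrom = "chr1", start = 20001, end = 30000))
  expect_false(call2)
  # island ending exactly at the promoter start does not overlap
  call3 <- promoter_mark_calls(gene, tibble::tibble(
    chrom = "chr1", start = 1000, end = 5000))
  expect_false(call3)
  # 1 bp of overlap is enough
  call4 <- promoter_mark_calls(gene, tibble::tibble(
    chrom = "chr1", start = 14999, end = 20000))
  expect_true(call4)
})

test_that("four-state classification is exhaustive, exclusive, and correct", {
  genes <- make_gene_table(tibble::tibble(
    gene_id = c("biv", "k4", "k27", "none"), chrom = "chr1", strand = "+",
    start = c(100000L, 300000L, 500000L, 700000L),
    end = c(120000L, 320000L, 520000L, 720000L)))
  islands <- dplyr::bind_rows(
    tibble::tibble(cell_type = "CD44", mark = "K4", chrom = "chr1",
                   start = c(99000, 299000), end = c(101000, 301000)),
    tibble::tibble(cell_type = "CD44", mark = "K27", chrom = "chr1",
                   start = c(98000, 498000), end = c(102000, 502000)))
  st <- classify_states(genes, islands, "CD44")
  expect_equal(nrow(st), 4)
  got <- setNames(as.character(st$state), st$gene_id)
  expect_equal(got[["biv"]], "bivalent")
  expect_equal(got[["k4"]], "K4-only")
  expect_equal(got[["k27"]], "K27-only")
  expect_equal(got[["none"]], "neither")
  # partition: one state per gene per cell type
  expect_equal(sum(table(st$state)), nrow(genes))
})

test_that("pattern table has 64 rows and labels planted categories", {
  mk_states <- function(gene_ids, s_hes, s44, s24) {
    purrr::map_dfr(list(c("hES", s_hes), c("CD44", s44), c("CD24", s24)),
                   function(p) tibble::tibble(
                     gene_id = gene_ids, cell_type = p[1],
                     k4 = p[2] %in% c("bivalent", "K4-only"),
                     k27 = p[2] %in% c("bivalent", "K27-only"),
                     state = factor(p[2], levels = c("bivalent", "K4-only",
                                                     "K27-only", "neither"))))
  }
  st <- dplyr::bind_rows(
    mk_states(sprintf("a%02d", 1:20), "bivalent", "K4-only", "K27-only"),
    mk_states(sprintf("b%02d", 1:5), "neither", "neither", "neither"))
  pt <- pattern_table(st)
  expect_equal(nrow(pt), 64)
  expect_equal(sum(pt$n_genes), 25)
  expect_equal(pt$n_genes[!is.na(pt$category) & pt$category == 3], 20)
  expect_equal(sum(pt$n_genes > 0), 2)

  # all seven categories sit on bivalent hES rows
  expect_true(all(pt$hES[!is.na(pt$category)] == "bivalent"))
  expect_equal(sum(!is.na(pt$category)), 7)

  # a gene missing one cell type is excluded and counted
  st_miss <- dplyr::bind_rows(st, mk_states("c01", "bivalent", "K4-only",
                                            "K4-only")[1:2, ])
  pt2 <- pattern_table(st_miss)
  expect_equal(attr(pt2, "n_excluded"), 1)
  expect_equal(sum(pt2$n_genes), 25)
})

test_that("K27 set algebra: shared + lost = progenitor K27 genes; planted sets recovered", {
  fx <- default_fixture()
  truth <- fx$ds$truth

  # noise-free: sets computed on ground-truth states are exact
  sets <- count_k27_gene_sets(truth$states)
  expect_equal(lengths(sets), c(shared = 60, lost = 40, gained = 40))

  # identity on called states
  called <- count_k27_gene_sets(fx$states)
  n_k27_cd44 <- sum(fx$states$k27[fx$states$cell_type == "CD44"])
  expect_equal(length(called$shared) + length(called$lost), n_k27_cd44)
  expect_length(intersect(called$lost, called$gained), 0)
})

test_that("called states recover >= 95% of planted truth labels", {
  fx <- default_fixture()
  cmp <- dplyr::inner_join(fx$states, fx$ds$truth$states,
                           by = c("gene_id", "cell_type"),
                           suffix = c("", ".truth"))
  acc <- mean(as.character(cmp$state) == as.character(cmp$state.truth))
  expect_gte(acc, 0.95)
})

test_that("K4-marked genes are expressed above K27-marked genes", {
  fx <- default_fixture()
  st44 <- dplyr::filter(fx$states, cell_type == "CD44")
  e <- dplyr::inner_join(st44, fx$expr, by = "gene_id")
  med_k4 <- median(e$median_a[e$state == "K4-only"])
  med_k27 <- median(e$median_a[e$state == "K27-only"])
  expect_gt(med_k4, med_k27)
})

test_that("promoter tag-count correlation behaves across coupling regimes", {
  fx <- default_fixture()
  genes <- fx$cfg$genes
  libA <- fx$ds$chip$CD44_K4

  # identical libraries correlate perfectly
  self <- promoter_tag_count_correlation(libA, libA, genes)
  expect_equal(self$correlation, 1.0)

  # independent draws from the same intensity correlate strongly
  cfg2 <- default_simulation_config(seed = 99)
  libA2 <- simulate_chip(cfg2, "CD44", "K4")
  rep_cor <- promoter_tag_count_correlation(libA, libA2, genes)
  expect_gt(rep_cor$correlation, 0.9)

  # two featureless libraries share no structure: correlation near 0
  cfgN1 <- simulation_config(genome = toy_genome(), seed = 31)
  cfgN2 <- simulation_config(genome = toy_genome(), seed = 32)
  nul <- promoter_tag_count_correlation(
    simulate_chip(cfgN1, "CD44", "input"),
    simulate_chip(cfgN2, "CD24", "input"), genes)
  expect_lt(abs(nul$correlation), 0.25)

  expect_error(promoter_tag_count_correlation(libA, libA2, genes[1, ]),
               "2 genes")
})
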