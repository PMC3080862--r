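test_that("the exact rate test matches enumeration and conventions", {
  expect_equal(dmr_test(0, 100, 0, 100), 1)               # no information
  expect_equal(dmr_test(10, 1e6, 0, 1e6), 2 * 0.5^10, tolerance = 1e-12)

  # symmetry: swapping the two sides preserves the p-value
  expect_equal(dmr_test(3, 1000, 12, 2000), dmr_test(12, 2000, 3, 1000))

  # independent oracle: stats::binom.test on the conditional binomial
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(0:50, 1)
    x_a <- if (n == 0) 0 else sample(0:n, 1)
    nn <- sample(list(c(1e5, 1e5), c(2e5, 1e5), c(1e5, 3e5)), 1)[[1]]
    got <- dmr_test(x_a, nn[1], n - x_a, nn[2])
    want <- if (n == 0) 1 else
      binom.test(x_a, n, p = nn[1] / sum(nn))$p.value
    expect_equal(got, want, tolerance = 1e-12,
                 info = sprintf("x_a=%d n=%d N=%g/%g", x_a, n, nn[1], nn[2]))
  }
})

test_that("DMR calling pools replicates and labels direction by rate deficit", {
  sc <- tibble::tibble(
    site_id = rep(c("s1", "s2", "s3"), each = 4),
    chrom = "chr1", pos = rep(c(100L, 200L, 300L), each = 4),
    library_id = rep(c("A1", "A2", "B1", "B2"), 3),
    cell_type = rep(c("CD44", "CD44", "CD24", "CD24"), 3),
    count = c(5, 5, 50, 55,      # s1: CD44 deficit -> CD44 hypermethylated
              60, 55, 5, 6,      # s2: CD24 deficit
              30, 30, 30, 30))   # s3: equal
  totals <- setNames(rep(1e5, 4), c("A1", "A2", "B1", "B2"))
  d <- call_dmrs(sc, totals = totals)
  dir <- setNames(d$direction, d$site_id)
  expect_equal(dir[["s1"]], "CD44-hyper")
  expect_equal(dir[["s2"]], "CD24-hyper")
  expect_equal(dir[["s3"]], "none")
  expect_lt(d$p_value[d$site_id == "s1"], 0.01)
  # equal normalized counts are never directional, whatever the p-value
  eq <- call_dmrs(tibble::tibble(
    site_id = "e", chrom = "chr1", pos = 1L,
    library_id = c("A1", "B1"), cell_type = c("CD44", "CD24"),
    count = c(20, 20)), totals = c(A1 = 1e5, B1 = 1e5))
  expect_equal(eq$direction, "none")
})

test_that("power: strongly differential sites at depth ~50 are nearly always caught", {
  # 60 strongly differential sites among 540 balanced ones, as in real data
  # where most of the genome is not differentially methylated
  n <- 600L
  diffsite <- seq_len(n) <= 60
  sites <- tibble::tibble(
    site_id = sprintf("d%03d", 1:n), chrom = "chr1",
    pos = seq(1000L, by = 10000L, length.out = n),
    meth_CD44 = ifelse(diffsite, 0.1, 0.3),
    meth_CD24 = ifelse(diffsite, 0.9, 0.3),
    weight = 1 / n)
  # unmethylated-side pooled expectation ~ 2 reps x 15000 / 600 x 0.9 ~ 45
  cfg <- simulation_config(genome = toy_genome(), msdk_sites = sites,
                           msdk_library_size = 15000, seed = 13)
  d <- call_dmrs(simulate_msdk(cfg))
  hit <- d$p_value < 0.01 & d$direction == "CD24-hyper"
  expect_gte(mean(hit[d$site_id %in% sites$site_id[diffsite]]), 0.95)
  # the balanced sites stay quiet
  expect_lte(mean(d$direction[!d$site_id %in% sites$site_id[diffsite]] !=
                    "none"), 0.05)
})

test_that("sites link to genes with strand-aware distances and region labels", {
  genes <- make_gene_table(tibble::tibble(
    gene_id = c("plus", "minus"), chrom = "chr1", strand = c("+", "-"),
    start = c(10000L, 400000L), end = c(30000L, 420000L)))
  # minus-strand TSS at 419999
  sites <- tibble::tibble(site_id = c("a", "b", "c", "d"),
                          chrom = "chr1",
                          pos = c(11500L, 15000L, 421999L, 2000L))
  links <- link_dmrs_to_genes(sites, genes)
  lk <- links[links$gene_id == "plus" & links$site_id == "a", ]
  expect_equal(lk$distance, 1500)
  expect_equal(lk$region, "promoter")

  lk <- links[links$gene_id == "plus" & links$site_id == "b", ]
  expect_equal(lk$distance, 5000)
  expect_equal(lk$region, "gene_body")

  lk <- links[links$gene_id == "minus" & links$site_id == "c", ]
  expect_equal(lk$distance, -2000)
  expect_equal(lk$region, "promoter")

  lk <- links[links$gene_id == "plus" & links$site_id == "d", ]
  expect_equal(lk$distance, -8000)
  expect_equal(lk$region, "neither")

  # links are capped at the radius
  far <- link_dmrs_to_genes(tibble::tibble(site_id = "z", chrom = "chr1",
                                           pos = 200000L),
                            genes[2, ], max_dist = 150000)
  expect_equal(nrow(far), 0)
})

test_that("positional profiles normalize within bins and dip where planted", {
  fx <- default_fixture()
  expr_classes <- dplyr::select(fx$expr, gene_id, expr_class)
  prof <- positional_association_profile(fx$dmr_links, expr_classes)
  sums <- dplyr::summarise(
    dplyr::group_by(prof, direction, bin_mid), s = sum(fraction),
    .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))

  # control profile over all sites is computable and normalized
  ctrl <- positional_association_profile(
    dplyr::mutate(fx$all_links, direction = "all"), expr_classes)
  sums2 <- dplyr::summarise(dplyr::group_by(ctrl, bin_mid), s = sum(fraction),
                            .groups = "drop")
  expect_true(all(abs(sums2$s - 1) < 1e-9))

  # promoter-adjacent bins of CD24-hypermethylated DMRs are dominated by
  # genes silenced in CD24 (CD44-high), unlike the all-sites control
  near <- function(p, dir) {
    d <- dplyr::filter(p, direction == dir, abs(bin_mid) <= 5000,
                       expr_class == "CD44-high")
    sum(d$n) / sum(dplyr::filter(p, direction == dir,
                                 abs(bin_mid) <= 5000)$n)
  }
  expect_gt(near(prof, "CD24-hyper"), near(ctrl, "all"))
})

test_that("mean expression by DMR group recovers the planted directions", {
  fx <- default_fixture()
  gm <- mean_expression_by_dmr_group(fx$dmr_links, fx$all_links, fx$expr,
                                     value = "median_b")  # CD24 expression
  prom24 <- gm[gm$region == "promoter" & gm$direction == "CD24-hyper", ]
  expect_lt(prom24$mean_expr, prom24$background_mean)

  gm44 <- mean_expression_by_dmr_group(fx$dmr_links, fx$all_links, fx$expr,
                                       value = "median_a")  # CD44 expression
  body44 <- gm44[gm44$region == "gene_body" & gm44$direction == "CD44-hyper", ]
  expect_gt(body44$mean_expr, body44$background_mean)

  # the background compared with itself shows no difference
  self <- mean_expression_by_dmr_group(
    dplyr::mutate(fx$all_links, direction = "all"), fx$all_links, fx$expr)
  expect_true(all(self$p_value > 0.2))
})
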