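test_that("window_counts bins tag 5' positions with half-open windows", {
  genome <- tibble::tibble(chrom = "chr1", length = 400)
  lib <- tag_library(tibble::tibble(chrom = "chr1", start = c(50L, 150L, 250L),
                                    end = c(86L, 186L, 286L)))
  wc <- window_counts(lib, genome, 200)
  expect_equal(wc$count, c(2, 1))

  expect_equal(window_counts(lib[0, ], genome, 200)$count, c(0, 0))

  boundary <- tag_library(tibble::tibble(chrom = "chr1", start = 200L,
                                         end = 236L))
  expect_equal(window_counts(boundary, genome, 200)$count, c(0, 1))

  # a minus-strand tag is counted at its 5' end (end - 1)
  minus <- tag_library(tibble::tibble(chrom = "chr1", start = 180L,
                                      end = 210L, strand = "-"))
  expect_equal(window_counts(minus, genome, 200)$count, c(0, 1))
})

test_that("eligibility threshold matches brute-force Poisson tail enumeration", {
  expect_equal(eligibility_threshold(1.0, 0.2), 3)
  expect_equal(eligibility_threshold(1e-9, 0.2), 1)

  # independent oracle: accumulate the pmf until the remaining tail drops
  # below p
  oracle <- function(lambda, p) {
    k <- 0
    cum <- 0
    repeat {
      tail_ge_kplus1 <- 1 - cum - dpois(k, lambda)
      cum <- cum + dpois(k, lambda)
      k <- k + 1
      if (tail_ge_kplus1 < p) break
    }
    max(k, 1)
  }
  for (lambda in c(0.05, 0.3, 1, 2.5, 5, 8.7, 20)) {
    for (p in c(0.2, 0.05, 0.001)) {
      expect_equal(eligibility_threshold(lambda, p), oracle(lambda, p),
                   info = sprintf("lambda=%g p=%g", lambda, p))
    }
  }
  expect_error(eligibility_threshold(0, 0.2), "positive")
})

test_that("island score is the sum of -ln Poisson pmf over eligible windows", {
  # geometry chosen so lambda_bg = 7 tags * 200 bp / (1400 * 1.0) = 1
  genome <- tibble::tibble(chrom = "chr1", length = 1400)
  pos <- c(0L, 50L, 100L, 200L, 210L, 220L, 230L)  # counts [3, 4] then zeros
  chip <- tag_library(tibble::tibble(chrom = "chr1", start = pos,
                                     end = pos + 20L))
  p <- island_params(window_size = 200, gap_size = 600, eligibility_p = 0.2,
                     fdr_cutoff = 0.5, effective_genome_fraction = 1)
  isl <- find_islands(chip, control = NULL, genome, p)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$n_windows, 2)
  expect_equal(isl$score, -log(dpois(3, 1)) - log(dpois(4, 1)),
               tolerance = 1e-12)
  expect_equal(isl$score, 6.97, tolerance = 1e-3)
})

test_that("island merging matches an exhaustive reference on toy chromosomes", {
  # independent reference: scan eligible window indices, merging while the
  # intervening ineligible run is <= gap windows (inclusive)
  ref_merge <- function(counts, l0, gap_windows) {
    el <- which(counts >= l0)
    if (length(el) == 0) return(NULL)
    runs <- list()
    cur <- c(el[1], el[1])
    for (i in el[-1]) {
      if (i - cur[2] - 1 <= gap_windows) cur[2] <- i
      else { runs <- c(runs, list(cur)); cur <- c(i, i) }
    }
    do.call(rbind, c(runs, list(cur)))
  }

  set.seed(42)
  for (case in 1:25) {
    nwin <- sample(10:50, 1)
    counts <- rpois(nwin, 1.2)
    genome <- tibble::tibble(chrom = "chr1", length = nwin * 200)
    tags <- tibble::tibble(
      chrom = "chr1",
      start = rep((seq_len(nwin) - 1L) * 200L, counts),
      end = rep((seq_len(nwin) - 1L) * 200L, counts) + 30L)
    if (nrow(tags) == 0) next
    lib <- tag_library(tags)
    prm <- island_params(window_size = 200, gap_size = 600,
                         fdr_cutoff = 0.999999,
                         effective_genome_fraction = 1)
    lambda <- nrow(tags) * 200 / (nwin * 200)
    l0 <- eligibility_threshold(lambda, prm$eligibility_p)
    got <- find_islands(lib, control = NULL, genome, prm)
    want <- ref_merge(counts, l0, 3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start, (want[, 1] - 1) * 200)
      expect_equal(got$end, want[, 2] * 200)
    }
  }
})

test_that("islands are sorted, non-overlapping, and score-additive", {
  fx <- default_fixture()
  isl <- dplyr::filter(fx$islands, cell_type == "CD44", mark == "K27")
  by_chr <- split(isl, isl$chrom)
  for (d in by_chr) {
    expect_true(all(diff(d$start) > 0))
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  expect_true(all(isl$q_value >= isl$p_value - 1e-12))

  # reconstruct one island's score from its eligible member windows
  big <- isl[which.max(isl$score), ]
  lib <- fx$ds$chip$CD44_K27
  wc <- window_counts(lib, fx$cfg$genome, 200)
  lambda <- nrow(lib) * 200 / (2e7 * 0.74)
  l0 <- eligibility_threshold(lambda, 0.2)
  members <- dplyr::filter(wc, chrom == big$chrom, start >= big$start,
                           end <= big$end, count >= l0)
  expect_equal(big$score, sum(-dpois(members$count, lambda, log = TRUE)),
               tolerance = 1e-8)
  expect_equal(big$n_windows, nrow(members))
})

test_that("raising the planted fold never decreases the island score", {
  genome <- toy_genome()
  scores <- vapply(c(2, 5, 12), function(fold) {
    island <- tibble::tibble(cell_type = "CD44", mark = "K27", chrom = "chr1",
                             start = 2000000L, end = 2010000L, fold = fold)
    cfg <- simulation_config(genome = genome, extra_islands = island,
                             seed = 21)
    isl <- find_islands(simulate_chip(cfg, "CD44", "K27"),
                        simulate_chip(cfg, "CD44", "input"), genome)
    hit <- dplyr::filter(tibble::as_tibble(isl), chrom == "chr1",
                         start < 2010000, end > 2000000)
    if (nrow(hit) == 0) 0 else max(hit$score)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("degenerate inputs raise instructive errors", {
  genome <- toy_genome()
  cfg <- simulation_config(genome = genome, seed = 2)
  chip <- simulate_chip(cfg, "CD44", "K27")
  empty <- chip[0, ]
  expect_error(find_islands(empty, NULL, genome), "empty")
  expect_error(find_islands(chip, empty, genome), "no-control")
  expect_error(island_params(window_size = 200, gap_size = 500), "gap_size")
})
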