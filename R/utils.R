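# Internal helpers shared across modules.

# Convert an interval tibble (chrom, start, end) to a GRanges. Internal
# coordinates are 0-based half-open; GRanges is 1-based closed, so shift on
# the way in and back out.
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# Indices of rows of `a` overlapping any row of `b` (>= 1 bp), plus the hits.
overlap_pairs <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(as_granges0(a), as_granges0(b))
  tibble(
    a_idx = S4Vectors::queryHits(hits),
    b_idx = S4Vectors::subjectHits(hits)
  )
}

check_genome <- function(genome) {
  stopifnot(is.data.frame(genome), all(c("chrom", "length") %in% names(genome)))
  if (nrow(genome) == 0 || any(genome$length <= 0)) {
    abort("genome must have at least one chromosome of positive length")
  }
  invisible(genome)
}

genome_length <- function(genome) sum(as.numeric(genome$length))

# 5' position of each tag: start on + / unstranded, end - 1 on -.
tag_pos5 <- function(tags) {
  ifelse(tags$strand == "-", tags$end - 1L, tags$start)
}
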