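#' Construct a tag library
#'
#' A tag library is a tibble of aligned sequence-tag positions (columns
#' `chrom`, `start`, `end`, `strand`; 0-based half-open coordinates) carrying
#' library metadata as attributes. It is the common currency for ChIP-seq,
#' SAGE-seq and MSDK-seq tag inputs.
#'
#' @param tags Data frame with columns `chrom`, `start`, `end` and optionally
#'   `strand` (`"+"`, `"-"` or `"*"`; missing column means `"*"`).
#' @param library_id Character scalar naming the library.
#' @param cell_type Cell population label (e.g. `"CD44"`, `"CD24"`, `"hES"`).
#' @param assay Assay label (e.g. `"K4"`, `"K27"`, `"input"`).
#' @return A tibble of class `tag_library`, sorted by chromosome and start,
#'   with attributes `library_id`, `cell_type`, `assay`.
#' @export
tag_library <- function(tags, library_id = "lib", cell_type = NA_character_,
                        assay = NA_character_) {
  tags <- as_tibble(tags)
  if (!"strand" %in% names(tags)) tags$strand <- "*"
  stopifnot(all(c("chrom", "start", "end") %in% names(tags)))
  if (nrow(tags) > 0) {
    if (any(tags$start < 0)) abort("tag start positions must be >= 0")
    bad <- which(tags$end <= tags$start)
    if (length(bad) > 0) {
      abort(sprintf("tag %d has end <= start (%d <= %d)",
                    bad[1], tags$end[bad[1]], tags$start[bad[1]]))
    }
    if (!all(tags$strand %in% c("+", "-", "*"))) {
      abort("strand must be one of '+', '-', '*'")
    }
  }
  tags <- arrange(tags[, c("chrom", "start", "end", "strand")],
                  .data$chrom, .data$start, .data$end)
  structure(tags,
            class = c("tag_library", class(tibble())),
            library_id = library_id, cell_type = cell_type, assay = assay)
}

#' Total tag count of a library
#' @param lib A [tag_library()].
#' @return Integer number of tags.
#' @export
total_tags <- function(lib) nrow(lib)

#' Read aligned tags from a BED file
#'
#' Reads a BED3/BED6 file (plain or gzip) of aligned tag positions into a
#' [tag_library()]. Coordinates are taken as-is (BED is already 0-based
#' half-open).
#'
#' @param path Path to the BED file.
#' @inheritParams tag_library
#' @return A [tag_library()].
#' @export
read_tag_bed <- function(path, library_id = basename(path),
                         cell_type = NA_character_, assay = NA_character_) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tag_library(tibble(chrom = character(), start = integer(),
                              end = integer(), strand = character()),
                       library_id, cell_type, assay))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields",
                  which(nf < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("malformed BED line %d: non-integer coordinates",
                  which(is.na(start) | is.na(end))[1]))
  }
  bad <- which(end <= start)
  if (length(bad) > 0) {
    abort(sprintf("BED line %d: end <= start", bad[1]))
  }
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6L, length(f))], ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  tag_library(tibble(chrom = chrom, start = start, end = end, strand = strand),
              library_id, cell_type, assay)
}

#' Write a tag library (or any interval tibble) as BED
#'
#' @param x Data frame with `chrom`, `start`, `end` and optional `strand`,
#'   `name`, `score` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand[!strand %in% c("+", "-")] <- "."
  out <- data.frame(x$chrom, x$start, x$end, name, score, strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Identify (and optionally collapse) duplicate tags
#'
#' Tags with identical `(chrom, start, strand)` are considered duplicates
#' (library PCR duplicates at the resolution of the 5' alignment position).
#' By default duplicates are only reported; `collapse = TRUE` keeps one tag
#' per duplicate group.
#'
#' @param lib A [tag_library()].
#' @param collapse Collapse duplicate groups to a single tag?
#' @return The library (collapsed if requested) with attribute
#'   `duplicate_fraction` = removed-or-removable / original count.
#' @seealso [duplicate_fraction()]
#' @export
deduplicate <- function(lib, collapse = TRUE) {
  n0 <- nrow(lib)
  meta <- attributes(lib)[c("library_id", "cell_type", "assay")]
  if (n0 == 0) {
    attr(lib, "duplicate_fraction") <- 0
    return(lib)
  }
  key <- paste(lib$chrom, lib$start, lib$strand, sep = "\r")
  dup <- duplicated(key)
  frac <- sum(dup) / n0
  out <- if (collapse) {
    tag_library(lib[!dup, , drop = FALSE], meta$library_id, meta$cell_type,
                meta$assay)
  } else {
    lib
  }
  attr(out, "duplicate_fraction") <- frac
  out
}

#' @rdname deduplicate
#' @export
duplicate_fraction <- function(lib) {
  f <- attr(lib, "duplicate_fraction")
  if (is.null(f)) f <- attr(deduplicate(lib, collapse = FALSE),
                            "duplicate_fraction")
  f
}

#' Read a gene annotation table
#'
#' Accepts a refFlat-style TSV with columns `gene_id`, `symbol` (optional),
#' `chrom`, `strand`, `start`, `end` (0-based half-open). Multiple records
#' sharing a `gene_id` are collapsed to the longest span. The strand-aware
#' TSS is computed: `start` for `+` genes, `end - 1` for `-` genes.
#'
#' @param path Path to the annotation TSV (with header).
#' @return A gene tibble: `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
read_gene_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"symbol" %in% names(x)) x$symbol <- x$gene_id
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(x)))
  make_gene_table(x)
}

#' Build a validated gene table from a data frame
#'
#' @param x Data frame with `gene_id`, `chrom`, `strand`, `start`, `end` and
#'   optional `symbol`.
#' @return A gene tibble with strand-aware `tss`; duplicate `gene_id`s
#'   collapsed to the longest span.
#' @export
make_gene_table <- function(x) {
  x <- as_tibble(x)
  if (!"symbol" %in% names(x)) x$symbol <- x$gene_id
  if (!all(x$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  if (any(x$end <= x$start)) abort("gene end must exceed start")
  x %>%
    mutate(.len = .data$end - .data$start) %>%
    group_by(.data$gene_id) %>%
    arrange(dplyr::desc(.data$.len), .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) %>%
    select("gene_id", "symbol", "chrom", "start", "end", "strand", "tss") %>%
    arrange(.data$chrom, .data$start)
}

#' Promoter windows for chromatin-mark calls
#'
#' The chromatin-call promoter window is TSS +/- `flank` bp, clipped at
#' chromosome bounds when a genome is given.
#'
#' @param genes Gene tibble (see [make_gene_table()]).
#' @param flank Half-width in bp (default 5000).
#' @param genome Optional genome tibble (`chrom`, `length`) for clipping.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_windows <- function(genes, flank = 5000, genome = NULL) {
  out <- genes %>%
    mutate(start = pmax(0, .data$tss - flank),
           end = .data$tss + flank) %>%
    select("gene_id", "chrom", "start", "end")
  if (!is.null(genome)) {
    out <- out %>%
      left_join(genome, by = "chrom") %>%
      mutate(end = pmin(.data$end, .data$length)) %>%
      select(-"length")
  }
  out
}

#' Library-size-normalized coverage track
#'
#' Counts tag 5' positions in non-overlapping windows and scales them to a
#' common depth of 10 million tags, the convention used for browser-style
#' coverage comparison across libraries.
#'
#' @param lib A [tag_library()].
#' @param genome Genome tibble (`chrom`, `length`).
#' @param window Window size in bp (default 10).
#' @param target Depth to scale to (default 1e7 tags).
#' @return Tibble `chrom`, `start`, `end`, `value` for windows with
#'   non-zero coverage (bedGraph-ready).
#' @export
scale_profile <- function(lib, genome, window = 10, target = 1e7) {
  check_genome(genome)
  stopifnot(window >= 1)
  if (nrow(lib) == 0) abort("cannot scale an empty library (total tags = 0)")
  factor <- target / nrow(lib)
  wc <- window_counts(lib, genome, window)
  wc %>%
    filter(.data$count > 0) %>%
    mutate(value = .data$count * factor) %>%
    select("chrom", "start", "end", "value")
}

#' Write a coverage track as bedGraph
#' @param track Tibble `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}
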