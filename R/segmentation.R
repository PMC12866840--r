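#' Build exon + non-exonic pairs in reading orientation
#'
#' Walks a chromosome layout in its reading orientation and pairs every exon
#' with the adjacent downstream NE interval: on the positive orientation the
#' NE immediately to an exon's right (pairs ordered left to right), on the
#' negative orientation the NE immediately to its left (pairs ordered right
#' to left). A dangling NE at the start of the reading direction, which has
#' no exon upstream of it, is accumulated into the first pair's `ne_len`, so
#' pair totals always conserve chromosome length exactly.
#'
#' @param layout A [chrom_layout].
#' @return A tibble with one row per exon in reading order: `pair`,
#'   `exon_start`, `exon_end`, `exon_len`, `ne_start`, `ne_end` (the
#'   principal adjacent gap; may be empty), `ne_len` (gap plus any
#'   accumulated dangling NE), `total_len`. Zero exons give a zero-row
#'   tibble.
#' @export
build_pairs <- function(layout) {
  ex <- layout_exons(layout)
  chrom_length <- attr(layout, "chrom_length")
  orientation <- attr(layout, "orientation")
  n <- nrow(ex)
  empty <- tibble(
    pair = integer(), exon_start = integer(), exon_end = integer(),
    exon_len = numeric(), ne_start = integer(), ne_end = integer(),
    ne_len = numeric(), total_len = numeric()
  )
  if (n == 0) return(empty)
  ex <- arrange(ex, .data$start)
  if (orientation == "positive") {
    ne_start <- ex$end
    ne_end <- c(ex$start[-1], chrom_length)
    out <- tibble(
      pair = seq_len(n),
      exon_start = ex$start, exon_end = ex$end,
      exon_len = as.numeric(ex$end - ex$start),
      ne_start = ne_start, ne_end = ne_end,
      ne_len = as.numeric(ne_end - ne_start)
    )
    out$ne_len[1] <- out$ne_len[1] + ex$start[1]  # dangling leading NE
  } else {
    idx <- rev(seq_len(n))  # reading right -> left
    ne_start <- c(0L, ex$end[-n])[idx]
    ne_end <- ex$start[idx]
    out <- tibble(
      pair = seq_len(n),
      exon_start = ex$start[idx], exon_end = ex$end[idx],
      exon_len = as.numeric((ex$end - ex$start)[idx]),
      ne_start = ne_start, ne_end = ne_end,
      ne_len = as.numeric(ne_end - ne_start)
    )
    out$ne_len[1] <- out$ne_len[1] + (chrom_length - ex$end[n])  # dangling trailing NE
  }
  mutate(out, total_len = .data$exon_len + .data$ne_len)
}

#' Detect hinge elements among exon + NE pairs
#'
#' A hinge is a short exon plus its adjacent NE, totalling at most
#' `hinge_max` bp (inclusive; default 300 bp, one to two nucleosomes). Hinges
#' are hypothesised transcription-engaged spacers separating packing domains,
#' and are the split points of chromosome segmentation.
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param hinge_max Inclusive threshold in bp on `exon_len + ne_len`.
#' @return The subset of `pairs` that qualify as hinges, with `span_start`,
#'   `span_end` covering the contiguous exon-plus-gap extent.
#' @export
detect_hinges <- function(pairs, hinge_max = 300) {
  if (length(hinge_max) != 1 || is.na(hinge_max) || hinge_max < 0) {
    abort("`hinge_max` must be a single non-negative number")
  }
  h <- filter(pairs, .data$total_len <= hinge_max)
  mutate(h,
    span_start = pmin(.data$exon_start, .data$ne_start),
    span_end = pmax(.data$exon_end, .data$ne_end)
  )
}

#' Split pairs into power-law segments at hinges
#'
#' Segments are maximal runs of consecutive non-hinge pairs; hinge pairs act
#' as delimiters and belong to no segment (`hinge_keep = "drop"`). The
#' alternative `"left"` keeps each triggering hinge inside the segment it
#' terminates, reproducing Mathematica's `SplitBy` semantics; content
#' differences are at most `hinge_max` bp per segment.
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param hinges Hinge tibble from [detect_hinges()] (a subset of `pairs`).
#' @param hinge_keep `"drop"` (default) or `"left"`.
#' @return A tibble with one row per segment: `segment`, `from_pair`,
#'   `to_pair`, `n_pairs`, `exon_bp`, `ne_bp`, `total_bp`, `span_start`,
#'   `span_end`.
#' @export
split_at_hinges <- function(pairs, hinges, hinge_keep = c("drop", "left")) {
  hinge_keep <- match.arg(hinge_keep)
  empty <- tibble(
    segment = integer(), from_pair = integer(), to_pair = integer(),
    n_pairs = integer(), exon_bp = numeric(), ne_bp = numeric(),
    total_bp = numeric(), span_start = integer(), span_end = integer()
  )
  if (nrow(pairs) == 0) return(empty)
  is_hinge <- pairs$pair %in% hinges$pair
  if (hinge_keep == "drop") {
    grp <- cumsum(is_hinge)
    keep <- !is_hinge
  } else {
    # a hinge closes the segment it belongs to
    grp <- c(0, cumsum(is_hinge)[-nrow(pairs)])
    keep <- rep(TRUE, nrow(pairs))
  }
  if (!any(keep)) return(empty)
  seg <- pairs[keep, , drop = FALSE]
  seg$.grp <- grp[keep]
  out <- seg |>
    group_by(.data$.grp) |>
    summarise(
      from_pair = min(.data$pair),
      to_pair = max(.data$pair),
      n_pairs = n(),
      exon_bp = sum(.data$exon_len),
      ne_bp = sum(.data$ne_len),
      total_bp = sum(.data$total_len),
      span_start = min(pmin(.data$exon_start, .data$ne_start)),
      span_end = max(pmax(.data$exon_end, .data$ne_end)),
      .groups = "drop"
    ) |>
    mutate(segment = row_number()) |>
    select("segment", "from_pair", "to_pair", "n_pairs", "exon_bp",
           "ne_bp", "total_bp", "span_start", "span_end")
  out
}

#' Segment a chromosome layout in one call
#'
#' Convenience wrapper: [build_pairs()], [detect_hinges()],
#' [split_at_hinges()].
#'
#' @inheritParams build_pairs
#' @inheritParams detect_hinges
#' @inheritParams split_at_hinges
#' @return A list with `pairs`, `hinges`, `segments`.
#' @export
segment_chromosome <- function(layout, hinge_max = 300,
                               hinge_keep = c("drop", "left")) {
  pairs <- build_pairs(layout)
  hinges <- detect_hinges(pairs, hinge_max)
  segments <- split_at_hinges(pairs, hinges, hinge_keep)
  list(pairs = pairs, hinges = hinges, segments = segments)
}

#' Map hinges onto gene bodies
#'
#' A gene contains a hinge when at least 1 bp of any hinge span intersects
#' its `[tx_start, tx_end)` body (half-open semantics).
#'
#' @param genes Gene-model tibble (same chromosome/orientation as the
#'   hinges).
#' @param hinges Hinge tibble from [detect_hinges()].
#' @return `genes` with a logical `has_hinge` column; the overall fraction is
#'   stored in `attr(, "fraction")`.
#' @export
hinge_gene_overlap <- function(genes, hinges) {
  gi <- IRanges::IRanges(genes$tx_start + 1L, genes$tx_end)
  hi <- IRanges::IRanges(hinges$span_start + 1L, hinges$span_end)
  out <- mutate(genes, has_hinge = IRanges::overlapsAny(gi, hi))
  attr(out, "fraction") <- if (nrow(out)) mean(out$has_hinge) else NA_real_
  out
}
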