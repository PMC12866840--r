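#' Exon-only randomisation of a chromosome layout
#'
#' Repositions the exon length multiset uniformly at random along the
#' chromosome without overlap, leaving everything else non-exonic. Placement
#' draws a uniform random arrangement directly (a random permutation of the
#' exon multiset with the free space split by a uniform random partition),
#' so every exon is retained and chromosome length is conserved exactly —
#' well inside the <=5% length / >=95% exon-content envelope asserted for
#' this null.
#'
#' @param layout A [chrom_layout].
#' @param seed Integer seed; a fixed seed is bit-reproducible.
#' @return A list (`mode`, `seed`, `length_change`, `exon_retained`,
#'   `layout`) where `layout` is the randomised [chrom_layout].
#' @export
randomize_exons <- function(layout, seed) {
  seed <- stopifnot_scalar_int(seed, "seed")
  chrom_length <- attr(layout, "chrom_length")
  ex <- layout_exons(layout)
  lens <- ex$end - ex$start
  total <- sum(lens)
  if (total > 0.95 * chrom_length) {
    abort("exon content exceeds 95% of the chromosome; placement infeasible")
  }
  withr::local_seed(seed)
  n <- length(lens)
  if (n > 0) {
    lens <- lens[sample.int(n)]
    free <- chrom_length - total
    # sorted uniform cut points of the free space = uniform random arrangement
    cuts <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L)
    starts <- cuts + cumsum(c(0, lens[-n]))
    new_ex <- tibble(start = starts, end = starts + lens)
  } else {
    new_ex <- tibble(start = integer(), end = integer())
  }
  new_layout <- chrom_layout(new_ex, chrom_length,
                             chrom = layout$chrom[1] %||% "chr1",
                             orientation = attr(layout, "orientation"))
  retained <- if (total > 0) {
    sum(with(layout_exons(new_layout), end - start)) / total
  } else 1
  stopifnot(abs(retained - 1) < 1e-12)
  list(
    mode = "exon_only", seed = seed,
    length_change = 0, exon_retained = retained,
    layout = new_layout
  )
}

#' Random permutation of exon + NE pairs
#'
#' Permutes the order of the (exon, NE) pairs along the chromosome while
#' preserving the pair multiset exactly: each exon keeps its adjacent NE, so
#' chromosome length and total exon content are conserved to the basepair,
#' and the hinge count is unchanged (hinge status is a per-pair property).
#' Coordinates are rebuilt by tiling the permuted pairs from position 0 in
#' the positive sense (exon then NE).
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param seed Integer seed.
#' @return A pair tibble in the permuted order with recomputed coordinates.
#' @export
permute_pairs <- function(pairs, seed) {
  seed <- stopifnot_scalar_int(seed, "seed")
  if (nrow(pairs) == 0) abort("`pairs` must be nonempty")
  withr::local_seed(seed)
  ord <- sample.int(nrow(pairs))
  out <- pairs[ord, , drop = FALSE]
  offs <- cumsum(c(0, out$total_len[-nrow(out)]))
  out |>
    mutate(
      pair = row_number(),
      exon_start = as.integer(offs),
      exon_end = as.integer(offs + .data$exon_len),
      ne_start = .data$exon_end,
      ne_end = as.integer(offs + .data$total_len)
    )
}

#' Null exon/intron ratios over gene windows after exon randomisation
#'
#' Applies [randomize_exons()] and recomputes E/I over the original gene
#' windows: for each window, E is the randomised exon bp overlapping it and
#' I the remainder. Under uniform placement the expected per-window ratio is
#' `f / (1 - f)` with `f` the chromosome-wide exonic fraction, independent
#' of window length; the summary reports the median ratio and the fitted
#' length exponent `n_hat` of E/I vs window length (zero for a true null).
#'
#' @param layout Original [chrom_layout].
#' @param windows Tibble of original gene spans (`start`, `end`, optionally
#'   `gene_id`).
#' @param seed Integer seed for the randomisation.
#' @return A list: `windows` (per-window `exon_bp`, `intron_bp`, `length`,
#'   `ei_ratio`), `median_ei`, `n_hat`, `fit` (the [ei_fit][fit_ei_vs_length]
#'   object), `n_excluded` (windows with I = 0), and the randomisation
#'   report.
#' @export
null_ei_distribution <- function(layout, windows, seed) {
  rand <- randomize_exons(layout, seed)
  ex_ir <- iranges_from_tbl(layout_exons(rand$layout))
  win_ir <- iranges_from_tbl(windows)
  hits <- IRanges::findOverlaps(win_ir, ex_ir)
  ov <- IRanges::pintersect(
    win_ir[S4Vectors::queryHits(hits)],
    ex_ir[S4Vectors::subjectHits(hits)]
  )
  exon_bp <- rep(0, length(win_ir))
  if (length(hits) > 0) {
    agg <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    exon_bp[as.integer(names(agg))] <- as.numeric(agg)
  }
  len <- as.numeric(windows$end - windows$start)
  w <- tibble(
    gene_id = windows$gene_id %||% paste0("w", seq_len(nrow(windows))),
    length = len,
    exon_bp = exon_bp,
    intron_bp = len - exon_bp,
    ei_ratio = if_else(len - exon_bp > 0, exon_bp / (len - exon_bp), NA_real_)
  )
  usable <- !is.na(w$ei_ratio)
  fit <- fit_ei_vs_length(w[usable, , drop = FALSE])
  list(
    windows = w,
    median_ei = median(w$ei_ratio[usable]),
    n_hat = fit$n_hat,
    fit = fit,
    n_excluded = sum(!usable),
    randomization = rand[c("mode", "seed", "length_change", "exon_retained")]
  )
}
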