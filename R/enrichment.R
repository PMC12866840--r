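split_ir_by_chrom <- function(tbl) {
  lapply(split(tbl, tbl$chrom), iranges_from_tbl)
}

#' Per-chromosome overlap fraction of query regions with peaks
#'
#' A query counts as overlapped when any peak intersects it by at least 1 bp
#' (half-open interval semantics). Chromosomes with no queries are skipped.
#'
#' @param queries Tibble with `chrom`, `start`, `end` (e.g. hinge spans or
#'   random controls).
#' @param peaks Peak tibble with `chrom`, `start`, `end`.
#' @return Tibble per chromosome: `chrom`, `n_queries`, `n_overlap`,
#'   `fraction`.
#' @export
overlap_fraction <- function(queries, peaks) {
  if (nrow(queries) == 0) abort("`queries` is empty")
  qs <- split_ir_by_chrom(queries)
  ps <- split_ir_by_chrom(peaks)
  out <- map(names(qs), function(ch) {
    q <- qs[[ch]]
    p <- ps[[ch]] %||% IRanges::IRanges()
    ov <- IRanges::overlapsAny(q, p)
    tibble(chrom = ch, n_queries = length(q), n_overlap = sum(ov),
           fraction = mean(ov))
  })
  arrange(bind_rows(out), .data$chrom)
}

#' Random fixed-size control regions per chromosome
#'
#' Places `n` uniformly random regions of a fixed size on each chromosome
#' (typically matching the hinge count per chromosome). Controls may overlap
#' each other and other features; excluding such overlaps would bias sparse
#' chromosomes.
#'
#' @param n_per_chrom Named integer vector: regions per chromosome.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param size Region size in bp (default 300).
#' @param seed Integer seed.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
random_control <- function(n_per_chrom, chrom_lengths, size = 300, seed = 1) {
  seed <- stopifnot_scalar_int(seed, "seed")
  if (is.null(names(n_per_chrom))) abort("`n_per_chrom` must be named by chromosome")
  if (any(!names(n_per_chrom) %in% names(chrom_lengths))) {
    abort("every chromosome in `n_per_chrom` needs a length")
  }
  if (any(size > chrom_lengths[names(n_per_chrom)])) {
    abort("`size` exceeds a chromosome length")
  }
  withr::local_seed(seed)
  out <- map(names(n_per_chrom), function(ch) {
    n <- n_per_chrom[[ch]]
    if (n == 0) return(NULL)
    start <- sample.int(chrom_lengths[[ch]] - size + 1L, n, replace = TRUE) - 1L
    tibble(chrom = ch, start = start, end = start + as.integer(size))
  })
  bind_rows(out)
}

#' Enrichment test of observed vs control overlap fractions
#'
#' Welch two-tailed t-test across chromosomes of the observed per-chromosome
#' overlap fractions against the matched random-control fractions.
#'
#' @param observed,control Tibbles from [overlap_fraction()] (or numeric
#'   vectors of per-chromosome fractions).
#' @return A tibble: `statistic`, `df`, `p_value`, `mean_observed`,
#'   `mean_control`, `n_chrom`.
#' @export
enrichment_test <- function(observed, control) {
  a <- if (is.data.frame(observed)) observed$fraction else observed
  b <- if (is.data.frame(control)) control$fraction else control
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 chromosomes")
  tt <- class_ttest(a, b)
  tibble(
    statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
    mean_observed = tt$mean_a, mean_control = tt$mean_b,
    n_chrom = length(a)
  )
}

peak_midpoints <- function(peaks) {
  mutate(peaks, mid = floor((.data$start + .data$end) / 2))
}

#' Median nearest-distance profile between two peak sets over genes
#'
#' Reduces both peak sets to their midpoints, buckets genes by their count of
#' a-peaks (1 up to 10; genes with more collapse into the top bucket), pools
#' for each bucket the distance from every a-midpoint inside the gene to the
#' nearest b-midpoint on the same chromosome, and reports the median of the
#' pooled (cumulative) distance distribution per bucket. Chromosomes without
#' b-peaks contribute no distances and are counted.
#'
#' @param peaks_a,peaks_b Peak tibbles with `chrom`, `start`, `end`.
#' @param genes Gene-model tibble (`chrom`, `tx_start`, `tx_end`).
#' @param max_count Top bucket (default 10).
#' @return A tibble per bucket: `a_count`, `n_genes`, `n_distances`,
#'   `median_distance`. Attribute `n_dropped` counts a-peaks on chromosomes
#'   with no b-peaks.
#' @export
distance_profile <- function(peaks_a, peaks_b, genes, max_count = 10) {
  a <- peak_midpoints(peaks_a)
  b <- peak_midpoints(peaks_b)
  b_by <- split(b$mid, b$chrom)
  # nearest b midpoint per a midpoint, per chromosome
  a$dist <- NA_real_
  for (ch in unique(a$chrom)) {
    i <- which(a$chrom == ch)
    bm <- sort(b_by[[ch]])
    if (is.null(bm) || length(bm) == 0) next
    pos <- findInterval(a$mid[i], bm)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(bm))
    a$dist[i] <- pmin(abs(a$mid[i] - bm[lo]), abs(a$mid[i] - bm[hi]))
  }
  n_dropped <- sum(is.na(a$dist))
  # assign a-peaks to genes
  gi <- IRanges::IRanges(genes$tx_start + 1L, genes$tx_end)
  out <- vector("list", nrow(genes))
  counts <- integer(nrow(genes))
  for (ch in unique(genes$chrom)) {
    g_idx <- which(genes$chrom == ch)
    a_idx <- which(a$chrom == ch & !is.na(a$dist))
    if (length(a_idx) == 0) next
    ai <- IRanges::IRanges(a$mid[a_idx] + 1L, width = 1L)
    hits <- IRanges::findOverlaps(ai, gi[g_idx])
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (k in seq_along(g_idx)) {
      sel <- a_idx[qh[sh == k]]
      counts[g_idx[k]] <- length(sel)
      out[[g_idx[k]]] <- a$dist[sel]
    }
  }
  bucket <- pmin(counts, max_count)
  res <- map(seq_len(max_count), function(bk) {
    sel <- which(bucket == bk & counts > 0)
    d <- unlist(out[sel])
    if (length(d) == 0) return(NULL)
    tibble(a_count = bk, n_genes = length(sel), n_distances = length(d),
           median_distance = median(d))
  })
  res <- bind_rows(res)
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Exon/NE composition and class of chromatin loops
#'
#' Intersects each loop span (from the minimum anchor start to the maximum
#' anchor end) with the exon intervals of a layout, sums exonic and
#' non-exonic bp, and classifies loops by contact frequency: `"strong"`
#' above `strong_min` contacts, `"transient"` below `transient_max`, and
#' `"mid"` in between (retained, not discarded). Loops with anchors on
#' different chromosomes are rejected and counted.
#'
#' @param loops Tibble with `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`, `frequency`.
#' @param layout A [chrom_layout] for the loops' chromosome.
#' @param strong_min,transient_max Frequency cuts (defaults >20 strong,
#'   <5 transient).
#' @return Tibble per loop: `chrom`, `span_start`, `span_end`, `span_bp`,
#'   `exon_bp`, `ne_bp`, `frequency`, `class`. Attribute `n_rejected` counts
#'   trans-chromosomal loops.
#' @export
loop_composition <- function(loops, layout, strong_min = 20, transient_max = 5) {
  cis <- loops$chrom_a == loops$chrom_b
  if (any(!cis)) {
    warn(sprintf("rejecting %d trans-chromosomal loop(s)", sum(!cis)))
  }
  lp <- loops[cis, , drop = FALSE]
  span_start <- pmin(lp$start_a, lp$start_b)
  span_end <- pmax(lp$end_a, lp$end_b)
  ex_ir <- iranges_from_tbl(layout_exons(layout))
  sp_ir <- IRanges::IRanges(span_start + 1L, span_end)
  hits <- IRanges::findOverlaps(sp_ir, ex_ir)
  exon_bp <- rep(0, length(sp_ir))
  if (length(hits) > 0) {
    ov <- IRanges::pintersect(sp_ir[S4Vectors::queryHits(hits)],
                              ex_ir[S4Vectors::subjectHits(hits)])
    agg <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    exon_bp[as.integer(names(agg))] <- as.numeric(agg)
  }
  out <- tibble(
    chrom = lp$chrom_a,
    span_start = span_start, span_end = span_end,
    span_bp = as.numeric(span_end - span_start),
    exon_bp = exon_bp,
    ne_bp = as.numeric(span_end - span_start) - exon_bp,
    frequency = lp$frequency,
    class = dplyr::case_when(
      lp$frequency > strong_min ~ "strong",
      lp$frequency < transient_max ~ "transient",
      TRUE ~ "mid"
    )
  )
  attr(out, "n_rejected") <- sum(!cis)
  out
}

#' Packing ratio of a signal track over regions
#'
#' The packing ratio of a region is the signal-covered bp within the region
#' divided by the region's NE bp; a power-law fit of ratio vs NE content (in
#' log10 space) quantifies how accessibility scales with the volumetric
#' material. Regions with zero NE are excluded and counted.
#'
#' @param signal Peak/coverage-interval tibble (`chrom`, `start`, `end`).
#' @param regions Tibble with `chrom`, `span_start`, `span_end`, `ne_bp`
#'   (e.g. from [loop_composition()] or segments with `span_*` columns).
#' @return A list: `regions` (with `covered_bp` and `packing_ratio`), `fit`
#'   (a [power_fit][fit_power_law] of ratio vs `ne_bp`, or `NULL` when under
#'   3 usable regions), `n_excluded`.
#' @export
packing_ratio <- function(signal, regions) {
  sig <- lapply(split(signal, signal$chrom),
                function(s) IRanges::reduce(iranges_from_tbl(
                  tibble(start = s$start, end = s$end))))
  covered <- rep(0, nrow(regions))
  for (ch in unique(regions$chrom)) {
    i <- which(regions$chrom == ch)
    s <- sig[[ch]]
    if (is.null(s) || length(s) == 0) next
    ri <- IRanges::IRanges(regions$span_start[i] + 1L, regions$span_end[i])
    hits <- IRanges::findOverlaps(ri, s)
    if (length(hits) == 0) next
    ov <- IRanges::pintersect(ri[S4Vectors::queryHits(hits)],
                              s[S4Vectors::subjectHits(hits)])
    agg <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    covered[i[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out <- mutate(regions,
    covered_bp = covered,
    packing_ratio = if_else(.data$ne_bp > 0, covered / .data$ne_bp, NA_real_)
  )
  usable <- filter(out, .data$ne_bp > 0, .data$packing_ratio > 0)
  fit <- if (nrow(usable) >= 3) {
    fit_power_law(usable, ne_bp, packing_ratio)
  } else NULL
  list(regions = out, fit = fit, n_excluded = sum(regions$ne_bp <= 0))
}

#' Mean mutation frequency and hinge fraction in ascending groups
#'
#' Sorts genes ascending by mutation frequency (ties broken by `gene_id` for
#' determinism), cuts them into `n_groups` contiguous, near-equal groups, and
#' reports each group's mean frequency and the fraction of its genes that
#' contain at least one hinge.
#'
#' @param gene_table Tibble with `gene_id`, `frequency` (>= 0) and logical
#'   `has_hinge` (e.g. joined from [hinge_gene_overlap()]).
#' @param n_groups Number of ascending groups.
#' @return Tibble per group: `group`, `n_genes`, `mean_frequency`,
#'   `hinge_fraction`.
#' @export
mutation_frequency_grouping <- function(gene_table, n_groups) {
  if (any(gene_table$frequency < 0)) abort("frequencies must be >= 0")
  n_groups <- stopifnot_scalar_int(n_groups, "n_groups", min = 1)
  if (n_groups > nrow(gene_table)) abort("more groups than genes")
  ord <- order(gene_table$frequency, gene_table$gene_id)
  gt <- gene_table[ord, , drop = FALSE]
  grp <- ceiling(seq_len(nrow(gt)) / (nrow(gt) / n_groups))
  gt$group <- pmin(as.integer(grp), n_groups)
  gt |>
    group_by(.data$group) |>
    summarise(
      n_genes = n(),
      mean_frequency = mean(.data$frequency),
      hinge_fraction = mean(.data$has_hinge),
      .groups = "drop"
    )
}

#' Mann-Whitney comparison of two genomic content distributions
#'
#' Utility for comparing a distribution of segment/domain DNA contents (bp)
#' against another sample (for example imaging-derived domain contents) with
#' a two-sided Mann-Whitney U test.
#'
#' @param content_a,content_b Numeric samples of genomic contents.
#' @return Tibble: `statistic` (U), `p_value`, `n_a`, `n_b`.
#' @export
compare_content_distributions <- function(content_a, content_b) {
  wt <- wilcox.test(content_a, content_b)
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_a = length(content_a), n_b = length(content_b))
}

#' Signal coverage per bp by element class
#'
#' Covered bp of a signal track within the exon vs NE intervals of a layout,
#' normalised per bp of each class (e.g. polymerase occupancy on exons vs
#' introns).
#'
#' @inheritParams packing_ratio
#' @param layout A [chrom_layout].
#' @return Tibble per class: `class`, `class_bp`, `covered_bp`,
#'   `coverage_per_bp`.
#' @export
class_coverage <- function(signal, layout) {
  sig <- IRanges::reduce(iranges_from_tbl(
    tibble(start = signal$start, end = signal$end)))
  per_class <- function(cls) {
    iv <- iranges_from_tbl(as_tibble(layout[layout$class == cls,
                                            c("start", "end")]))
    cov <- sum(IRanges::width(IRanges::intersect(iv, sig)))
    tibble(class = cls, class_bp = sum(IRanges::width(iv)),
           covered_bp = as.numeric(cov))
  }
  bind_rows(per_class("exon"), per_class("ne")) |>
    mutate(coverage_per_bp = .data$covered_bp / .data$class_bp)
}
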