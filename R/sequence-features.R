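as_dna_set <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) return(seqs)
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs)) {
    return(Biostrings::readDNAStringSet(seqs))
  }
  if (is.character(seqs)) return(Biostrings::DNAStringSet(seqs))
  abort("`seqs` must be a DNAStringSet, a FASTA path, or a named character vector")
}

region_views <- function(regions, dna) {
  missing_chrom <- setdiff(unique(regions$chrom), names(dna))
  if (length(missing_chrom) > 0) {
    abort(paste("sequences missing for:", paste(missing_chrom, collapse = ", ")))
  }
  lens <- setNames(Biostrings::width(dna), names(dna))
  if (any(regions$end > lens[regions$chrom])) {
    abort("regions extend beyond sequence bounds")
  }
  regions
}

#' GC content of genomic regions
#'
#' GC = (#G + #C) / (#A + #C + #G + #T) per region, with ambiguous bases (N)
#' excluded from the denominator. Fully ambiguous regions get `NA` and are
#' excluded from summaries. [gc_by_chrom()] reports the length-weighted mean
#' over regions per chromosome (weights = unambiguous bases).
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param seqs A `DNAStringSet` named by chromosome, a FASTA path, or a named
#'   character vector.
#' @return `regions` with columns `gc` and `acgt_bp` added.
#' @export
gc_content <- function(regions, seqs) {
  dna <- as_dna_set(seqs)
  regions <- region_views(regions, dna)
  counts <- matrix(0, nrow(regions), 2, dimnames = list(NULL, c("gc", "acgt")))
  for (ch in unique(regions$chrom)) {
    i <- which(regions$chrom == ch)
    v <- Biostrings::Views(dna[[ch]],
                           start = regions$start[i] + 1L, end = regions$end[i])
    af <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    counts[i, "gc"] <- af[, "C"] + af[, "G"]
    counts[i, "acgt"] <- rowSums(af)
  }
  acgt <- unname(counts[, "acgt"])
  mutate(regions,
    acgt_bp = acgt,
    gc = if_else(acgt > 0, unname(counts[, "gc"]) / acgt, NA_real_)
  )
}

#' @rdname gc_content
#' @param regions_gc Output of `gc_content()`.
#' @export
gc_by_chrom <- function(regions_gc) {
  regions_gc |>
    filter(!is.na(.data$gc)) |>
    group_by(.data$chrom) |>
    summarise(
      n_regions = n(),
      gc = sum(.data$gc * .data$acgt_bp) / sum(.data$acgt_bp),
      .groups = "drop"
    )
}

#' Fraction of regions containing a sequence motif
#'
#' Scans each region for a literal motif (default the CTCF core `CCCTC`) and,
#' with `both_strands = TRUE`, also for its reverse complement on the same
#' sequence. A region counts once regardless of hit multiplicity; overlapping
#' hits are allowed.
#'
#' @inheritParams gc_content
#' @param motif Literal motif over A/C/G/T.
#' @param both_strands Also scan the reverse complement.
#' @return `regions` with a logical `has_motif` column; [motif_by_chrom()]
#'   summarises the per-chromosome fraction.
#' @export
motif_fraction <- function(regions, seqs, motif = "CCCTC", both_strands = TRUE) {
  if (!grepl("^[ACGT]+$", motif)) abort("`motif` must be over A/C/G/T")
  dna <- as_dna_set(seqs)
  regions <- region_views(regions, dna)
  pats <- Biostrings::DNAString(motif)
  rc <- Biostrings::reverseComplement(pats)
  hit <- logical(nrow(regions))
  for (ch in unique(regions$chrom)) {
    i <- which(regions$chrom == ch)
    v <- Biostrings::Views(dna[[ch]],
                           start = regions$start[i] + 1L, end = regions$end[i])
    ss <- Biostrings::DNAStringSet(v)
    n1 <- Biostrings::vcountPattern(pats, ss)
    n2 <- if (both_strands) Biostrings::vcountPattern(rc, ss) else 0L
    hit[i] <- (n1 + n2) > 0
  }
  mutate(regions, has_motif = hit)
}

#' @rdname motif_fraction
#' @param regions_motif Output of `motif_fraction()`.
#' @export
motif_by_chrom <- function(regions_motif) {
  regions_motif |>
    group_by(.data$chrom) |>
    summarise(n_regions = n(), motif_fraction = mean(.data$has_motif),
              .groups = "drop")
}

#' Welch t-test between two classes of per-chromosome frequencies
#'
#' Two-sample, two-tailed, unequal-variance t-test with per-chromosome
#' frequencies as the test units.
#'
#' @param values_a,values_b Numeric vectors (one value per chromosome,
#'   at least 2 each).
#' @return A tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
class_ttest <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("need at least 2 chromosomes per class")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    abort("zero variance in both classes; t-test undefined")
  }
  tt <- t.test(values_a, values_b, var.equal = FALSE)
  tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(values_a), mean_b = mean(values_b),
    n_a = length(values_a), n_b = length(values_b)
  )
}
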