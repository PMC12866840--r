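#' Read gene annotations into a gene-model table
#'
#' Parses a gene annotation file into one row per transcript model with the
#' exon structure held in list-columns. All coordinates are 0-based half-open
#' internally; GTF input (1-based closed) is converted at the boundary.
#'
#' The gene class is assigned from the accession prefix where available:
#' `"NM"` accessions are `protein_coding`, `"NR"` accessions `non_coding`,
#' anything else `NA`.
#'
#' @param path Path to the annotation file.
#' @param dialect One of `"genepred"` (8-column TSV: name, chrom, strand,
#'   txStart, txEnd, exonCount, exonStarts, exonEnds, the last two
#'   comma-separated with a trailing comma), `"bed12"`, or `"gtf"`.
#' @param first_isoform If `TRUE`, keep only the first record encountered per
#'   `gene_id` in file order.
#' @return A tibble with columns `gene_id`, `gene_class`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `n_exons`, and list-columns `exon_starts`,
#'   `exon_ends`. Rejected records (malformed, or exons outside the transcript
#'   bounds) are dropped with a warning naming the offending lines; the count
#'   is available as `attr(x, "n_rejected")`.
#' @export
read_annotation <- function(path, dialect = c("genepred", "bed12", "gtf"),
                            first_isoform = FALSE) {
  dialect <- match.arg(dialect)
  genes <- switch(dialect,
    genepred = read_genepred(path),
    bed12 = read_bed12(path),
    gtf = read_gtf(path)
  )
  genes <- validate_gene_models(genes)
  if (first_isoform) {
    genes <- distinct(genes, .data$gene_id, .keep_all = TRUE)
  }
  genes
}

accession_class <- function(id) {
  dplyr::case_when(
    stringr::str_starts(id, "NM") ~ "protein_coding",
    stringr::str_starts(id, "NR") ~ "non_coding",
    TRUE ~ NA_character_
  )
}

parse_int_list <- function(x) {
  map(stringr::str_split(x, ","), function(v) {
    v <- v[nzchar(v)]
    suppressWarnings(as.integer(v))
  })
}

read_genepred <- function(path) {
  cols <- c("name", "chrom", "strand", "txStart", "txEnd",
            "exonCount", "exonStarts", "exonEnds")
  first <- readr::read_lines(path, n_max = 1)
  has_header <- any(stringr::str_detect(first, "txStart|exonStarts"))
  raw <- readr::read_tsv(path,
    col_names = if (has_header) TRUE else cols,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (has_header) raw <- select(raw, dplyr::all_of(cols))
  names(raw) <- cols
  line0 <- seq_len(nrow(raw)) + as.integer(has_header)
  starts <- parse_int_list(raw$exonStarts)
  ends <- parse_int_list(raw$exonEnds)
  tx_start <- suppressWarnings(as.integer(raw$txStart))
  tx_end <- suppressWarnings(as.integer(raw$txEnd))
  n_ex <- suppressWarnings(as.integer(raw$exonCount))
  bad <- is.na(tx_start) | is.na(tx_end) |
    map_lgl(starts, ~ any(is.na(.x)) || length(.x) == 0) |
    map_lgl(ends, ~ any(is.na(.x))) |
    map_int(starts, length) != map_int(ends, length) |
    (!is.na(n_ex) & map_int(starts, length) != n_ex)
  if (any(bad)) {
    warn(sprintf(
      "dropping %d malformed genePred record(s) at line(s) %s",
      sum(bad), paste(line0[bad], collapse = ", ")
    ))
  }
  tibble(
    gene_id = raw$name[!bad],
    gene_class = accession_class(raw$name[!bad]),
    chrom = raw$chrom[!bad],
    strand = raw$strand[!bad],
    tx_start = tx_start[!bad],
    tx_end = tx_end[!bad],
    exon_starts = starts[!bad],
    exon_ends = ends[!bad]
  )
}

read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  tibble(
    gene_id = gr$name %||% paste0("bed_", seq_along(gr)),
    gene_class = accession_class(gr$name %||% ""),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    tx_start = GenomicRanges::start(gr) - 1L,
    tx_end = GenomicRanges::end(gr),
    exon_starts = map(seq_along(gr), function(i) IRanges::start(blocks[[i]]) - 1L),
    exon_ends = map(seq_along(gr), function(i) IRanges::end(blocks[[i]]))
  )
}

read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  id <- gr$transcript_id %||% gr$gene_id
  ex <- tibble(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  ex |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      tx_start = min(.data$start),
      tx_end = max(.data$end),
      exon_starts = list(.data$start),
      exon_ends = list(.data$end),
      .groups = "drop"
    ) |>
    mutate(gene_class = accession_class(.data$gene_id)) |>
    select("gene_id", "gene_class", "chrom", "strand",
           "tx_start", "tx_end", "exon_starts", "exon_ends")
}

validate_gene_models <- function(genes) {
  ord <- map2(genes$exon_starts, genes$exon_ends, function(s, e) {
    o <- order(s)
    list(s = s[o], e = e[o])
  })
  genes$exon_starts <- map(ord, "s")
  genes$exon_ends <- map(ord, "e")
  ok_iv <- map2_lgl_safe(genes$exon_starts, genes$exon_ends,
                         function(s, e) all(s < e))
  in_tx <- pmap(list(genes$exon_starts, genes$exon_ends,
                     genes$tx_start, genes$tx_end),
                function(s, e, t0, t1) all(s >= t0) && all(e <= t1))
  in_tx <- unlist(in_tx)
  bad <- !ok_iv | !in_tx
  if (any(bad)) {
    warn(sprintf(
      "rejecting %d record(s) with exons outside transcript bounds or empty intervals: %s",
      sum(bad), paste(utils::head(genes$gene_id[bad], 10), collapse = ", ")
    ))
  }
  out <- genes[!bad, , drop = FALSE]
  out$n_exons <- map_int(out$exon_starts, length)
  out <- select(out, "gene_id", "gene_class", "chrom", "strand",
                "tx_start", "tx_end", "n_exons", "exon_starts", "exon_ends")
  attr(out, "n_rejected") <- sum(bad)
  out
}

map2_lgl_safe <- function(x, y, f) unlist(map2(x, y, f))

#' Per-gene exon/intron content metrics
#'
#' Computes total exonic bp (E), intronic bp (I = L - E), gene-body length
#' (L = tx_end - tx_start) and the E/I ratio for each gene model. Single-exon
#' genes (I = 0) get an `NA` ratio and are flagged.
#'
#' @param genes A gene-model tibble from [read_annotation()] or
#'   [generate_genome()].
#' @return A tibble with `gene_id`, `chrom`, `exon_bp`, `intron_bp`, `length`,
#'   `ei_ratio`, `single_exon`.
#' @export
gene_metrics <- function(genes) {
  exon_bp <- map2_lgl_safe(genes$exon_starts, genes$exon_ends,
                           function(s, e) sum(e - s))
  len <- genes$tx_end - genes$tx_start
  intron_bp <- len - exon_bp
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    exon_bp = as.numeric(exon_bp),
    intron_bp = as.numeric(intron_bp),
    length = as.numeric(len),
    ei_ratio = if_else(intron_bp > 0, exon_bp / intron_bp, NA_real_),
    single_exon = intron_bp == 0
  )
}

# chromosome layout -----------------------------------------------------------

#' Construct a chromosome layout from disjoint exon intervals
#'
#' A chromosome layout is the substrate of segmentation: an ordered set of
#' disjoint exon intervals plus their complement (non-exonic, NE) tiling
#' `[0, chrom_length)`.
#'
#' @param exons Tibble with 0-based half-open `start`, `end` columns; intervals
#'   must be disjoint (touching intervals are merged).
#' @param chrom_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param orientation `"positive"` or `"negative"` reading orientation,
#'   consumed downstream by pair construction.
#' @return A tibble of class `chrom_layout` with columns `chrom`, `start`,
#'   `end`, `length`, `class` (`"exon"`/`"ne"`), and attributes
#'   `chrom_length`, `orientation`.
#' @export
chrom_layout <- function(exons, chrom_length, chrom = "chr1",
                         orientation = c("positive", "negative")) {
  orientation <- match.arg(orientation)
  chrom_length <- stopifnot_scalar_int(chrom_length, "chrom_length", min = 1)
  # merge overlapping intervals but keep touching ones distinct: adjacency is
  # meaningful (an exon followed by a zero-length gap is still its own pair)
  ex <- IRanges::reduce(iranges_from_tbl(exons), min.gapwidth = 0L)
  if (length(ex) > 0 && max(IRanges::end(ex)) > chrom_length) {
    abort("exon intervals extend beyond `chrom_length`")
  }
  ne <- IRanges::gaps(ex, start = 1L, end = chrom_length)
  tb <- bind_rows(
    mutate(tbl_from_iranges(ex), class = "exon"),
    mutate(tbl_from_iranges(ne), class = "ne")
  ) |>
    arrange(.data$start) |>
    mutate(chrom = chrom, length = .data$end - .data$start) |>
    select("chrom", "start", "end", "length", "class")
  new_chrom_layout(tb, chrom_length, orientation)
}

new_chrom_layout <- function(tb, chrom_length, orientation,
                             omitted_n = 0L, omitted_frac = 0) {
  structure(
    tb,
    chrom_length = as.integer(chrom_length),
    orientation = orientation,
    omitted_n = omitted_n,
    omitted_frac = omitted_frac,
    class = c("chrom_layout", class(tibble()))
  )
}

#' @export
print.chrom_layout <- function(x, ...) {
  cat(sprintf(
    "<chrom_layout> %s, %s orientation, %d bp, %d exon / %d NE intervals\n",
    x$chrom[1] %||% "?", attr(x, "orientation"), attr(x, "chrom_length"),
    sum(x$class == "exon"), sum(x$class == "ne")
  ))
  NextMethod()
}

#' Exon intervals of a layout
#' @param layout A `chrom_layout`.
#' @return Tibble of exon `start`, `end`.
#' @export
layout_exons <- function(layout) {
  i <- layout$class == "exon"
  tibble(start = layout$start[i], end = layout$end[i])
}

#' Project exon models onto a chromosome
#'
#' Projects the exons of a set of gene models (one chromosome, one strand)
#' onto the chromosome axis. Exact duplicate exons collapse to one; exons that
#' partially overlap another exon with different boundaries (multi-start /
#' multi-stop events) are omitted entirely, and the omitted fraction is
#' recorded. The complement of the surviving exons is non-exonic (NE).
#'
#' @param genes Gene-model tibble restricted to one chromosome and strand.
#' @param chrom_length Chromosome length (bp).
#' @param orientation Reading orientation of the resulting layout.
#' @return A [chrom_layout] with attributes `omitted_n` (number of distinct
#'   exons omitted) and `omitted_frac` (fraction of distinct exons omitted).
#' @export
project_exons <- function(genes, chrom_length,
                          orientation = c("positive", "negative")) {
  orientation <- match.arg(orientation)
  if (length(unique(genes$chrom)) > 1) {
    abort("`genes` must be restricted to a single chromosome")
  }
  if (length(unique(genes$strand)) > 1) {
    abort("`genes` must be restricted to a single strand")
  }
  ex <- tibble(
    start = unlist(genes$exon_starts),
    end = unlist(genes$exon_ends)
  )
  over_end <- ex$end > chrom_length
  if (any(over_end)) {
    warn(sprintf("rejecting %d exon(s) beyond chromosome length", sum(over_end)))
    ex <- ex[!over_end, , drop = FALSE]
  }
  ex <- distinct(ex, .data$start, .data$end)
  ir <- iranges_from_tbl(ex)
  hits <- IRanges::findOverlaps(ir, ir)
  clash <- S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)
  omit <- unique(S4Vectors::queryHits(hits)[clash])
  keep <- setdiff(seq_len(nrow(ex)), omit)
  layout <- chrom_layout(ex[keep, , drop = FALSE], chrom_length,
                         chrom = genes$chrom[1] %||% "chr1",
                         orientation = orientation)
  attr(layout, "omitted_n") <- length(omit)
  attr(layout, "omitted_frac") <-
    if (nrow(ex) > 0) length(omit) / nrow(ex) else 0
  layout
}

#' Write / read a layout as 4-column BED
#'
#' The element class (`exon`/`ne`) is stored in the BED name field. Reading
#' back reproduces identical intervals.
#'
#' @param layout A `chrom_layout`.
#' @param path Output file.
#' @return `write_layout_bed()` returns `path` invisibly; `read_layout_bed()`
#'   returns a `chrom_layout`.
#' @export
write_layout_bed <- function(layout, path) {
  readr::write_tsv(
    tibble(chrom = layout$chrom, start = layout$start, end = layout$end,
           name = layout$class),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_layout_bed
#' @param chrom_length,orientation Layout attributes (not stored in BED).
#' @export
read_layout_bed <- function(path, chrom_length, orientation = "positive") {
  tb <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                        col_types = "ciic", progress = FALSE)
  chrom_layout(
    tb[tb$name == "exon", c("start", "end")],
    chrom_length = chrom_length,
    chrom = tb$chrom[1],
    orientation = orientation
  )
}
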