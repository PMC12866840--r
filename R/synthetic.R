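#' Specification of a synthetic genome
#'
#' Defines the study conditions a synthetic genome emulates. Three
#' architectures are supported for the per-gene intron total given the exon
#' total E:
#' * `power_law`: `I = E^gamma / p` (times log-normal noise `sigma_log10`),
#'   the volumetric packing-domain regime with `gamma` between 2 and 3;
#' * `linear`: `I = c * E`, the beads-on-a-string regime;
#' * `random_null`: gene length drawn directly and E/I drawn independently of
#'   length, the no-geometry null (exons then placed uniformly within the
#'   gene body as ~`null_exon_length` bp pieces).
#'
#' Genes are laid end to end along each chromosome; each gene boundary
#' carries, with probability `hinge_rate`, a planted hinge spacer (a short
#' exon plus short NE, jointly under 300 bp). When `exonic_fraction` is set,
#' intergenic gaps are sized to bring the chromosome-wide exonic fraction
#' down to the target (gaps can only dilute; a target above the genes' own
#' exonic fraction is infeasible and raises an error). The default `NULL`
#' adds no padding.
#'
#' @param n_chromosomes,n_genes Number of chromosomes and total genes.
#' @param architecture `"power_law"`, `"linear"` or `"random_null"`.
#' @param gamma,p Power-law exponent (in `[2, 3]`) and depth scalar (bp).
#' @param linear_c Slope of the linear architecture.
#' @param sigma_log10 Log10-normal noise on the intron total.
#' @param exon_bp_range Log-uniform range of per-gene exon totals (bp).
#' @param exon_count Exons per gene (fixed; keeps the gene-level and
#'   pair-level scaling laws mutually consistent).
#' @param exon_alpha Dirichlet concentration of the exon-length split.
#' @param intron_split `"coupled"` (introns proportional to adjacent
#'   exon^gamma; default) or `"dirichlet"` (symmetric Dirichlet(1)).
#' @param null_gene_length_range,null_ei_range,null_exon_length Gene length
#'   range (bp), E/I ratio range, and exon piece size of the `random_null`
#'   architecture.
#' @param min_intron_bp Floor on intron lengths of the power-law/linear
#'   architectures (default 300, the hinge threshold): guarantees intra-genic
#'   pairs never register as hinges, so planted spacers are the only domain
#'   delimiters. Genes whose intron total cannot support `exon_count - 1`
#'   floored introns get a reduced exon count.
#' @param hinge_rate Probability that a gene boundary carries a hinge spacer.
#' @param exonic_fraction Target chromosome-wide exonic fraction in
#'   (0, 0.5), or `NULL` for no intergenic padding.
#' @return A validated `genome_spec` list.
#' @export
genome_spec <- function(n_chromosomes = 1, n_genes = 2000,
                        architecture = c("power_law", "linear", "random_null"),
                        gamma = 2.3, p = 5000, linear_c = 9,
                        sigma_log10 = 0.1,
                        exon_bp_range = c(3000, 30000),
                        exon_count = 8, exon_alpha = 1,
                        intron_split = c("coupled", "dirichlet"),
                        null_gene_length_range = c(5e4, 5e5),
                        null_ei_range = c(0.04, 0.4),
                        null_exon_length = 200,
                        min_intron_bp = 300,
                        hinge_rate = 1,
                        exonic_fraction = NULL) {
  architecture <- match.arg(architecture)
  intron_split <- match.arg(intron_split)
  if (architecture == "power_law" && (gamma < 2 || gamma > 3)) {
    abort("`gamma` must lie in [2, 3] for the power-law architecture")
  }
  if (!is.null(exonic_fraction) &&
      (exonic_fraction <= 0 || exonic_fraction >= 0.5)) {
    abort("`exonic_fraction` must lie in (0, 0.5)")
  }
  if (any(exon_bp_range < 1) || diff(exon_bp_range) < 0) {
    abort("`exon_bp_range` must be an increasing range of lengths >= 1")
  }
  if (hinge_rate < 0 || hinge_rate > 1) abort("`hinge_rate` must be in [0, 1]")
  if (exon_count < 2) abort("`exon_count` must be >= 2")
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      n_genes = as.integer(n_genes),
      architecture = architecture, gamma = gamma, p = p,
      linear_c = linear_c, sigma_log10 = sigma_log10,
      exon_bp_range = exon_bp_range, exon_count = as.integer(exon_count),
      exon_alpha = exon_alpha, intron_split = intron_split,
      min_intron_bp = as.integer(min_intron_bp),
      null_gene_length_range = null_gene_length_range,
      null_ei_range = null_ei_range,
      null_exon_length = null_exon_length,
      hinge_rate = hinge_rate, exonic_fraction = exonic_fraction
    ),
    class = "genome_spec"
  )
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# split `total` into `k` integer parts proportional to `w`, each >= 1
split_int <- function(total, w) {
  k <- length(w)
  if (total < k) return(NULL)
  cuts <- round(cumsum(w) / sum(w) * (total - k))
  parts <- diff(c(0, cuts)) + 1L
  parts
}

rloguniform <- function(n, lo, hi) {
  round(10^runif(n, log10(lo), log10(hi)))
}

#' Generate a synthetic annotated genome
#'
#' Draws gene models per [genome_spec()], assembles each chromosome as an
#' ordered alternation of exon and NE intervals (genes, hinge spacers and
#' optional intergenic gaps), and returns the gene table, per-chromosome
#' layouts and a provenance record sufficient to recompute every expectation.
#' Bit-reproducible under a fixed seed.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed.
#' @return A list: `genes` (gene-model tibble as from [read_annotation()]),
#'   `layouts` (named list of [chrom_layout]s, positive orientation),
#'   `hinges` (tibble of planted hinge spacer coordinates), `provenance`
#'   (list with the spec, seed, per-gene draws and realised per-chromosome
#'   statistics).
#' @export
generate_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  seed <- stopifnot_scalar_int(seed, "seed")
  withr::local_seed(seed)
  n_chr <- spec$n_chromosomes
  per_chr <- diff(round(seq(0, spec$n_genes, length.out = n_chr + 1)))
  chroms <- sprintf("chr%d", seq_len(n_chr))
  genes_all <- list(); layouts <- list(); hinges_all <- list(); prov <- list()
  gene_counter <- 0
  for (ci in seq_len(n_chr)) {
    ng <- per_chr[ci]
    draws <- draw_genes(spec, ng)
    asm <- assemble_chromosome(spec, draws, chroms[ci], gene_counter)
    gene_counter <- gene_counter + ng
    genes_all[[ci]] <- asm$genes
    layouts[[ci]] <- asm$layout
    hinges_all[[ci]] <- asm$hinges
    prov[[ci]] <- asm$stats
  }
  names(layouts) <- chroms
  genes <- bind_rows(genes_all)
  list(
    genes = genes,
    layouts = layouts,
    hinges = bind_rows(hinges_all),
    provenance = list(
      spec = unclass(spec), seed = seed,
      gene_draws = bind_rows(map(seq_len(n_chr), function(ci) {
        mutate(prov[[ci]]$draws, chrom = chroms[ci])
      })),
      chrom_stats = bind_rows(map(seq_len(n_chr), function(ci) {
        mutate(prov[[ci]]$summary, chrom = chroms[ci])
      }))
    )
  )
}

# per-gene E, I totals and exon/intron length splits
draw_genes <- function(spec, ng) {
  if (spec$architecture == "random_null") {
    L <- rloguniform(ng, spec$null_gene_length_range[1],
                     spec$null_gene_length_range[2])
    r <- 10^runif(ng, log10(spec$null_ei_range[1]), log10(spec$null_ei_range[2]))
    E <- pmax(round(L * r / (1 + r)), spec$null_exon_length)
    I <- L - E
    k <- pmax(2L, as.integer(round(E / spec$null_exon_length)))
  } else {
    E <- rloguniform(ng, spec$exon_bp_range[1], spec$exon_bp_range[2])
    noise <- 10^rnorm(ng, 0, spec$sigma_log10)
    I_raw <- switch(spec$architecture,
      power_law = E^spec$gamma / spec$p,
      linear = spec$linear_c * E
    )
    k <- rep(spec$exon_count, ng)
    I <- pmax(round(I_raw * noise), k - 1L)  # one bp minimum per intron
  }
  tibble(E = as.numeric(E), I = as.numeric(I), k = as.integer(k))
}

# build one gene's alternating exon/intron lengths
gene_pieces <- function(spec, E, I, k) {
  if (spec$architecture == "random_null") {
    w <- rdirichlet1(k, spec$exon_alpha)
    exon_len <- split_int(E, w)
    if (is.null(exon_len)) {
      exon_len <- rep(floor(E / k), k)
      exon_len[1] <- exon_len[1] + E - sum(exon_len)
    }
    # uniform placement of exons within the gene body: gaps from a uniform
    # random partition of the non-exonic space (including gene flanks)
    g <- stats::rexp(k + 1)
    intron_len <- split_int(I, g)
    if (is.null(intron_len)) intron_len <- c(I, rep(0L, k))
    return(list(exon_len = exon_len, intron_len = intron_len[2:k],
                lead = intron_len[1], trail = intron_len[k + 1]))
  }
  # introns carry a floor of `min_intron_bp` so intra-genic exon+NE pairs can
  # never fall under the hinge threshold: planted spacers are the only hinges
  k <- min(k, max(2L, 1L + as.integer(I %/% spec$min_intron_bp)))
  w <- rdirichlet1(k, spec$exon_alpha)
  exon_len <- split_int(E, w)
  if (is.null(exon_len)) {
    exon_len <- rep(floor(E / k), k)
    exon_len[1] <- exon_len[1] + E - sum(exon_len)
  }
  # terminal exon is the largest (3' exons carry the long UTR in real genes);
  # keeps the final pair, whose downstream NE is intergenic, off the hinge scale
  imax <- which.max(exon_len)
  exon_len <- c(exon_len[-imax], exon_len[imax])
  n_int <- k - 1L
  floor_bp <- min(spec$min_intron_bp, I %/% n_int)
  rest <- I - floor_bp * n_int
  v <- switch(spec$intron_split,
    coupled = exon_len[-k]^spec$gamma,
    dirichlet = rdirichlet1(n_int, 1)
  )
  extra <- if (rest >= n_int) split_int(rest, v) else NULL
  if (is.null(extra)) {
    extra <- rep(0L, n_int)
    if (rest > 0) extra[which.max(v)] <- as.integer(rest)
  }
  intron_len <- floor_bp + extra
  list(exon_len = exon_len, intron_len = intron_len, lead = 0L, trail = 0L)
}

assemble_chromosome <- function(spec, draws, chrom, gene_offset) {
  ng <- nrow(draws)
  pieces <- pmap(draws, function(E, I, k) gene_pieces(spec, E, I, k))
  gene_len <- map_dbl(pieces, function(p) {
    sum(p$exon_len) + sum(p$intron_len) + p$lead + p$trail
  })
  has_hinge <- runif(ng) < spec$hinge_rate
  h_exon <- ifelse(has_hinge, sample(60:120, ng, replace = TRUE), 0L)
  h_ne <- ifelse(has_hinge, sample(80:160, ng, replace = TRUE), 0L)
  total_E <- sum(draws$E) + sum(h_exon)
  total_len_nogap <- sum(gene_len) + sum(h_exon + h_ne)
  if (!is.null(spec$exonic_fraction)) {
    chrom_len <- round(total_E / spec$exonic_fraction)
    total_gap <- chrom_len - total_len_nogap
    if (total_gap < 0) {
      abort(sprintf(
        "infeasible spec: genes alone are %.1f%% exonic, above the %.1f%% target",
        100 * total_E / total_len_nogap, 100 * spec$exonic_fraction
      ))
    }
    gaps <- split_int(total_gap + ng, stats::rexp(ng)) - 1L
    if (is.null(gaps)) gaps <- rep(0L, ng)
  } else {
    gaps <- rep(0L, ng)
    chrom_len <- total_len_nogap
  }
  # walk: [gene][gap][hinge_exon][hinge_ne] ... per gene
  pos <- 0
  exon_starts <- integer(0); exon_ends <- integer(0)
  genes <- vector("list", ng); hinges <- vector("list", ng)
  for (gi in seq_len(ng)) {
    p <- pieces[[gi]]
    tx_start <- pos
    pos <- pos + p$lead
    k <- length(p$exon_len)
    es <- integer(k); ee <- integer(k)
    for (j in seq_len(k)) {
      es[j] <- pos
      ee[j] <- pos + p$exon_len[j]
      pos <- ee[j] + if (j < k) p$intron_len[j] else 0L
    }
    pos <- pos + p$trail
    tx_end <- pos
    genes[[gi]] <- tibble(
      gene_id = sprintf("NM_%06d", gene_offset + gi),
      gene_class = "protein_coding",
      chrom = chrom, strand = "+",
      tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
      n_exons = k,
      exon_starts = list(es), exon_ends = list(ee)
    )
    exon_starts <- c(exon_starts, es); exon_ends <- c(exon_ends, ee)
    pos <- pos + gaps[gi]
    if (has_hinge[gi]) {
      hs <- pos
      exon_starts <- c(exon_starts, hs)
      exon_ends <- c(exon_ends, hs + h_exon[gi])
      pos <- hs + h_exon[gi] + h_ne[gi]
      hinges[[gi]] <- tibble(
        chrom = chrom, span_start = as.integer(hs), span_end = as.integer(pos),
        exon_len = h_exon[gi], ne_len = h_ne[gi]
      )
    }
  }
  chrom_len <- pos
  if (chrom_len > .Machine$integer.max) {
    abort(paste0(
      "chromosome length ", format(chrom_len, big.mark = ","),
      " exceeds 32-bit interval coordinates; increase `n_chromosomes`"
    ))
  }
  layout <- chrom_layout(tibble(start = exon_starts, end = exon_ends),
                         chrom_length = chrom_len, chrom = chrom,
                         orientation = "positive")
  list(
    genes = bind_rows(genes),
    layout = layout,
    hinges = bind_rows(hinges),
    stats = list(
      draws = mutate(draws, gene_id = sprintf("NM_%06d", gene_offset + seq_len(ng))),
      summary = tibble(
        chrom_length = chrom_len,
        exon_bp = sum(exon_ends - exon_starts),
        exonic_fraction = sum(exon_ends - exon_starts) / chrom_len,
        n_hinges_planted = sum(has_hinge)
      )
    )
  )
}

#' Specification of synthetic sequence / peak / loop features
#'
#' Controls the contrasts planted by [generate_sequence()],
#' [generate_peaks()] and [generate_loops()]: class-specific GC, per-region
#' motif-planting probabilities, hinge-targeted peak probability and
#' background peak intensity, and the contact-frequency ranges of strong and
#' transient loops.
#'
#' @param gc_background,gc_exon,gc_hinge Base compositions by region class.
#' @param motif_rate_hinge,motif_rate_exon Probability a hinge/exon region
#'   receives a planted motif copy (background chance hits add on top).
#' @param peak_rate_hinge Probability a hinge receives a targeted peak.
#' @param peak_bg_per_bp Background peak intensity (peaks per bp).
#' @param peak_width_meanlog,peak_width_sdlog Log-normal peak widths.
#' @param loop_strong_freq,loop_transient_freq Contact-frequency ranges.
#' @return A `feature_spec` list.
#' @export
feature_spec <- function(gc_background = 0.41, gc_exon = 0.41, gc_hinge = 0.53,
                         motif_rate_hinge = 0.37, motif_rate_exon = 0.22,
                         peak_rate_hinge = 0.03, peak_bg_per_bp = 1e-5,
                         peak_width_meanlog = log(200), peak_width_sdlog = 0.4,
                         loop_strong_freq = c(21, 60),
                         loop_transient_freq = c(1, 4)) {
  probs <- c(gc_background, gc_exon, gc_hinge, motif_rate_hinge,
             motif_rate_exon, peak_rate_hinge)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  structure(
    list(
      gc_background = gc_background, gc_exon = gc_exon, gc_hinge = gc_hinge,
      motif_rate_hinge = motif_rate_hinge, motif_rate_exon = motif_rate_exon,
      peak_rate_hinge = peak_rate_hinge, peak_bg_per_bp = peak_bg_per_bp,
      peak_width_meanlog = peak_width_meanlog,
      peak_width_sdlog = peak_width_sdlog,
      loop_strong_freq = loop_strong_freq,
      loop_transient_freq = loop_transient_freq
    ),
    class = "feature_spec"
  )
}

gc_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

#' Generate chromosome sequence with class-specific GC and planted motifs
#'
#' Draws i.i.d. bases with the background GC, overwrites exon intervals with
#' exon-GC bases and hinge spans with hinge-GC bases, then plants one motif
#' copy (`CCCTC`) at a uniform position within each hinge/exon region with
#' the class-specific probability. Background chance hits occur on top of
#' planting, as in real sequence.
#'
#' @param layout A [chrom_layout].
#' @param fspec A [feature_spec()].
#' @param hinges Optional tibble of hinge spans (`span_start`, `span_end`)
#'   taking GC/motif precedence over the exon class.
#' @param seed Integer seed.
#' @param motif Motif to plant.
#' @return A `DNAStringSet` of length 1 named by the chromosome.
#' @export
generate_sequence <- function(layout, fspec, hinges = NULL, seed = 1,
                              motif = "CCCTC") {
  seed <- stopifnot_scalar_int(seed, "seed")
  withr::local_seed(seed)
  chrom_len <- attr(layout, "chrom_length")
  bases <- c("A", "C", "G", "T")
  seq_v <- sample(bases, chrom_len, replace = TRUE,
                  prob = gc_probs(fspec$gc_background))
  ex <- layout_exons(layout)
  overwrite <- function(seq_v, start, end, gc) {
    idx <- sequence(end - start, from = start + 1L)
    seq_v[idx] <- sample(bases, length(idx), replace = TRUE,
                         prob = gc_probs(gc))
    seq_v
  }
  if (nrow(ex) > 0) seq_v <- overwrite(seq_v, ex$start, ex$end, fspec$gc_exon)
  if (!is.null(hinges) && nrow(hinges) > 0) {
    seq_v <- overwrite(seq_v, hinges$span_start, hinges$span_end, fspec$gc_hinge)
  }
  plant <- function(seq_v, start, end, rate) {
    m <- strsplit(motif, "")[[1]]
    wide <- which((end - start) >= length(m))
    hitit <- wide[runif(length(wide)) < rate]
    for (i in hitit) {
      s0 <- start[i] + sample.int(end[i] - start[i] - length(m) + 1L, 1L) - 1L
      seq_v[(s0 + 1):(s0 + length(m))] <- m
    }
    seq_v
  }
  if (nrow(ex) > 0) seq_v <- plant(seq_v, ex$start, ex$end, fspec$motif_rate_exon)
  if (!is.null(hinges) && nrow(hinges) > 0) {
    seq_v <- plant(seq_v, hinges$span_start, hinges$span_end,
                   fspec$motif_rate_hinge)
  }
  out <- Biostrings::DNAStringSet(paste(seq_v, collapse = ""))
  names(out) <- layout$chrom[1] %||% "chr1"
  out
}

#' Generate a synthetic peak set
#'
#' Background peaks arise from a uniform Poisson process at
#' `peak_bg_per_bp`; each hinge additionally receives, with probability
#' `peak_rate_hinge`, a targeted peak starting inside it. Widths are
#' log-normal. An `exon_rate_per_bp` adds exon-targeted peaks (a Poisson
#' count per exon with a start inside the exon), emulating marks that track
#' transcribed sequence.
#'
#' @param layout A [chrom_layout].
#' @param fspec A [feature_spec()].
#' @param hinges Optional hinge spans for targeted peaks.
#' @param mark Name recorded in the `name` column.
#' @param exon_rate_per_bp Intensity of exon-targeted peaks (default 0).
#' @param seed Integer seed.
#' @return Peak tibble: `chrom`, `start`, `end`, `name`.
#' @export
generate_peaks <- function(layout, fspec, hinges = NULL, mark = "mark",
                           exon_rate_per_bp = 0, seed = 1) {
  seed <- stopifnot_scalar_int(seed, "seed")
  withr::local_seed(seed)
  chrom_len <- attr(layout, "chrom_length")
  chrom <- layout$chrom[1] %||% "chr1"
  widths <- function(n) {
    pmax(10L, as.integer(round(rlnorm(n, fspec$peak_width_meanlog,
                                      fspec$peak_width_sdlog))))
  }
  out <- list()
  n_bg <- rpois(1, fspec$peak_bg_per_bp * chrom_len)
  if (n_bg > 0) {
    s <- sample.int(chrom_len, n_bg, replace = TRUE) - 1L
    out$bg <- tibble(chrom = chrom, start = s, end = s + widths(n_bg))
  }
  if (!is.null(hinges) && nrow(hinges) > 0) {
    sel <- which(runif(nrow(hinges)) < fspec$peak_rate_hinge)
    if (length(sel) > 0) {
      s <- hinges$span_start[sel] +
        map_int(hinges$span_end[sel] - hinges$span_start[sel],
                function(w) sample.int(w, 1L)) - 1L
      out$hinge <- tibble(chrom = chrom, start = s, end = s + widths(length(s)))
    }
  }
  if (exon_rate_per_bp > 0) {
    ex <- layout_exons(layout)
    n_per <- rpois(nrow(ex), exon_rate_per_bp * (ex$end - ex$start))
    sel <- rep(seq_len(nrow(ex)), n_per)
    if (length(sel) > 0) {
      s <- ex$start[sel] +
        map_int(ex$end[sel] - ex$start[sel], function(w) sample.int(w, 1L)) - 1L
      out$exon <- tibble(chrom = chrom, start = s, end = s + widths(length(s)))
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  res |>
    mutate(end = pmin(.data$end, chrom_len), name = mark) |>
    arrange(.data$start)
}

#' Generate synthetic chromatin loops
#'
#' Strong loops (contact frequency above the strong cut) coincide with
#' power-law segment spans; transient loops (below the transient cut) are
#' uniform random spans with lengths resampled from the same segments.
#'
#' @param segments Segment tibble from [split_at_hinges()] (with
#'   `span_start`, `span_end`).
#' @param fspec A [feature_spec()].
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length bp.
#' @param n_strong,n_transient Number of loops per class.
#' @param anchor_bp Anchor width.
#' @param seed Integer seed.
#' @return Loop tibble: `chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`,
#'   `end_b`, `frequency`, `class`.
#' @export
generate_loops <- function(segments, fspec, chrom = "chr1", chrom_length,
                           n_strong = 50, n_transient = 50, anchor_bp = 500,
                           seed = 1) {
  seed <- stopifnot_scalar_int(seed, "seed")
  if (nrow(segments) == 0) abort("`segments` must be nonempty")
  withr::local_seed(seed)
  mk <- function(span_start, span_end, freq, cls) {
    a <- pmin(anchor_bp, pmax(1, floor((span_end - span_start) / 2)))
    tibble(
      chrom_a = chrom, start_a = span_start, end_a = span_start + a,
      chrom_b = chrom, start_b = span_end - a, end_b = span_end,
      frequency = freq, class = cls
    )
  }
  si <- sample.int(nrow(segments), n_strong, replace = TRUE)
  strong <- mk(
    segments$span_start[si], segments$span_end[si],
    sample(fspec$loop_strong_freq[1]:fspec$loop_strong_freq[2],
           n_strong, replace = TRUE),
    "strong"
  )
  len <- sample(pmax(segments$span_end - segments$span_start, 2L),
                n_transient, replace = TRUE)
  s0 <- map_int(chrom_length - len + 1L, function(m) sample.int(m, 1L)) - 1L
  transient <- mk(
    s0, s0 + len,
    sample(fspec$loop_transient_freq[1]:fspec$loop_transient_freq[2],
           n_transient, replace = TRUE),
    "transient"
  )
  bind_rows(strong, transient)
}
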