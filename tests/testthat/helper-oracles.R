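# Brute-force reference implementations used as independent oracles.
# These deliberately use plain loops / O(n*m) scans, not the package's code
# paths, so agreement is evidence rather than tautology.

# pair construction by explicit walk over layout elements
brute_pairs <- function(exons, chrom_len, orientation = "positive") {
  ex <- exons[order(exons$start), , drop = FALSE]
  n <- nrow(ex)
  if (n == 0) return(data.frame(exon_len = numeric(), ne_len = numeric()))
  if (orientation == "positive") {
    out <- data.frame(exon_len = numeric(n), ne_len = numeric(n))
    for (i in seq_len(n)) {
      gap_end <- if (i < n) ex$start[i + 1] else chrom_len
      out$exon_len[i] <- ex$end[i] - ex$start[i]
      out$ne_len[i] <- gap_end - ex$end[i]
    }
    out$ne_len[1] <- out$ne_len[1] + ex$start[1]
  } else {
    out <- data.frame(exon_len = numeric(n), ne_len = numeric(n))
    for (j in seq_len(n)) {
      i <- n - j + 1  # right -> left
      gap_start <- if (i > 1) ex$end[i - 1] else 0
      out$exon_len[j] <- ex$end[i] - ex$start[i]
      out$ne_len[j] <- ex$start[i] - gap_start
    }
    out$ne_len[1] <- out$ne_len[1] + (chrom_len - ex$end[n])
  }
  out
}

# exhaustive split: walk pairs, cut at hinges
brute_split <- function(exon_len, ne_len, hinge_max) {
  segs <- list()
  cur_e <- 0; cur_n <- 0; cur_k <- 0
  for (i in seq_along(exon_len)) {
    if (exon_len[i] + ne_len[i] <= hinge_max) {
      if (cur_k > 0) segs[[length(segs) + 1]] <- c(cur_e, cur_n, cur_k)
      cur_e <- 0; cur_n <- 0; cur_k <- 0
    } else {
      cur_e <- cur_e + exon_len[i]
      cur_n <- cur_n + ne_len[i]
      cur_k <- cur_k + 1
    }
  }
  if (cur_k > 0) segs[[length(segs) + 1]] <- c(cur_e, cur_n, cur_k)
  if (length(segs) == 0) {
    return(data.frame(exon_bp = numeric(), ne_bp = numeric(), n_pairs = numeric()))
  }
  m <- do.call(rbind, segs)
  data.frame(exon_bp = m[, 1], ne_bp = m[, 2], n_pairs = m[, 3])
}

# O(n*m) overlap indicator (0-based half-open)
brute_overlap <- function(q_start, q_end, p_start, p_end) {
  vapply(seq_along(q_start), function(i) {
    any(p_start < q_end[i] & p_end > q_start[i])
  }, logical(1))
}

# O(n*m) nearest-midpoint distance
brute_nearest <- function(a, b) {
  vapply(a, function(x) min(abs(x - b)), numeric(1))
}

# random disjoint exon set on [0, chrom_len)
random_exon_layout <- function(n, chrom_len, max_len = 400) {
  lens <- sample.int(max_len, n, replace = TRUE)
  free <- chrom_len - sum(lens)
  stopifnot(free > 0)
  cuts <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L)
  starts <- cuts + cumsum(c(0L, lens[-n]))
  tibble::tibble(start = starts, end = starts + lens)
}

# tiny genePred fixture written to a temp file
write_genepred_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gp", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
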