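toy_layout <- function(orientation = "positive") {
  chrom_layout(tibble::tibble(start = c(100L, 500L), end = c(200L, 600L)),
               1000, orientation = orientation)
}

test_that("pair construction matches the brute-force walk in both orientations", {
  ex <- tibble::tibble(start = c(100L, 500L), end = c(200L, 600L))
  for (ori in c("positive", "negative")) {
    got <- build_pairs(chrom_layout(ex, 1000, orientation = ori))
    ref <- brute_pairs(ex, 1000, ori)
    expect_equal(got$exon_len, ref$exon_len)
    expect_equal(got$ne_len, ref$ne_len)
    expect_equal(sum(got$total_len), 1000)  # conservation incl. dangling NE
  }
  # explicit values: dangling NE accumulates into the first reading-order pair
  pos <- build_pairs(toy_layout("positive"))
  expect_equal(pos$ne_len, c(400, 400))  # leading [0,100) attaches to pair 1
  neg <- build_pairs(toy_layout("negative"))
  expect_equal(neg$exon_start, c(500L, 100L))  # right -> left
  expect_equal(neg$ne_len, c(700, 100))  # trailing [600,1000) attaches to pair 1
})

test_that("pair construction handles degenerate layouts", {
  one <- chrom_layout(tibble::tibble(start = 0L, end = 500L), 500)
  p <- build_pairs(one)
  expect_equal(nrow(p), 1)
  expect_equal(p$ne_len, 0)
  empty <- chrom_layout(tibble::tibble(start = integer(), end = integer()), 100)
  expect_equal(nrow(build_pairs(empty)), 0)
})

test_that("random layouts conserve chromosome length through pairing", {
  withr::local_seed(11)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    len <- sample(20000:60000, 1)
    ex <- random_exon_layout(n, len)
    for (ori in c("positive", "negative")) {
      p <- build_pairs(chrom_layout(ex, len, orientation = ori))
      ref <- brute_pairs(ex, len, ori)
      expect_equal(p$exon_len, ref$exon_len)
      expect_equal(p$ne_len, ref$ne_len)
      expect_equal(sum(p$total_len), len)
    }
  }
})

test_that("hinge detection is an inclusive threshold scan", {
  pairs <- tibble::tibble(
    pair = 1:4,
    exon_start = 0L, exon_end = 0L, ne_start = 0L, ne_end = 0L,
    exon_len = c(100, 5000, 200, 3000), ne_len = c(150, 20000, 50, 9000)
  )
  pairs$total_len <- pairs$exon_len + pairs$ne_len
  h <- detect_hinges(pairs, 300)
  expect_equal(h$pair, c(1L, 3L))
  # boundary inclusivity: 150 + 150 = 300 qualifies
  b <- pairs; b$exon_len[2] <- 150; b$ne_len[2] <- 150; b$total_len[2] <- 300
  expect_true(2L %in% detect_hinges(b, 300)$pair)
  expect_equal(nrow(detect_hinges(pairs, 100)), 0)
  expect_error(detect_hinges(pairs, -1), "hinge_max")
})

test_that("splitting at hinges yields maximal non-hinge runs with summed content", {
  pairs <- tibble::tibble(
    pair = 1:4,
    exon_start = c(0L, 250L, 25250L, 25500L),
    exon_end = c(100L, 5250L, 25450L, 28500L),
    ne_start = c(100L, 5250L, 25450L, 28500L),
    ne_end = c(250L, 25250L, 25500L, 37500L),
    exon_len = c(100, 5000, 200, 3000), ne_len = c(150, 20000, 50, 9000)
  )
  pairs$total_len <- pairs$exon_len + pairs$ne_len
  segs <- split_at_hinges(pairs, detect_hinges(pairs, 300))
  expect_equal(nrow(segs), 2)
  expect_equal(segs$exon_bp, c(5000, 3000))
  expect_equal(segs$ne_bp, c(20000, 9000))
  # no hinges -> one segment; all hinges -> none
  expect_equal(nrow(split_at_hinges(pairs, detect_hinges(pairs, 0))), 1)
  expect_equal(nrow(split_at_hinges(pairs, detect_hinges(pairs, 1e9))), 0)
  # SplitBy-style alternative keeps the closing hinge inside its segment
  left <- split_at_hinges(pairs, detect_hinges(pairs, 300), hinge_keep = "left")
  expect_equal(sum(left$exon_bp) + sum(left$ne_bp),
               sum(pairs$exon_len) + sum(pairs$ne_len))
})

test_that("segmentation matches the exhaustive reference on random pair lists", {
  withr::local_seed(23)
  for (i in 1:100) {
    n <- sample(1:50, 1)
    ex <- random_exon_layout(n, 60000)
    lay <- chrom_layout(ex, 60000,
                        orientation = sample(c("positive", "negative"), 1))
    p <- build_pairs(lay)
    segs <- split_at_hinges(p, detect_hinges(p, 300))
    ref <- brute_split(p$exon_len, p$ne_len, 300)
    expect_equal(segs$exon_bp, ref$exon_bp)
    expect_equal(segs$ne_bp, ref$ne_bp)
    expect_equal(segs$n_pairs, as.integer(ref$n_pairs))
  }
})

test_that("raising hinge_max never lowers the hinge count", {
  withr::local_seed(5)
  ex <- random_exon_layout(80, 100000)
  p <- build_pairs(chrom_layout(ex, 100000))
  counts <- vapply(c(0, 100, 300, 1000, 5000),
                   function(h) nrow(detect_hinges(p, h)), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(nrow(split_at_hinges(p, detect_hinges(p, 0))), 1)
})

test_that("segment + hinge content conserves chromosome length", {
  withr::local_seed(9)
  for (ori in c("positive", "negative")) {
    ex <- random_exon_layout(60, 80000, max_len = 250)
    lay <- chrom_layout(ex, 80000, orientation = ori)
    sg <- segment_chromosome(lay, 300)
    expect_equal(sum(sg$segments$total_bp) + sum(sg$hinges$total_len), 80000)
  }
})

test_that("hinge-to-gene overlap uses half-open 1 bp semantics", {
  hinges <- tibble::tibble(pair = 1L, span_start = 100L, span_end = 400L)
  genes <- tibble::tibble(
    gene_id = c("NM_a", "NM_b"), chrom = "chr1",
    tx_start = c(399L, 400L), tx_end = c(900L, 900L)
  )
  out <- hinge_gene_overlap(genes, hinges)
  expect_equal(out$has_hinge, c(TRUE, FALSE))
  expect_equal(attr(out, "fraction"), 0.5)
  # brute-force agreement on a random instance
  withr::local_seed(31)
  ex <- random_exon_layout(50, 60000)
  lay <- chrom_layout(ex, 60000)
  p <- build_pairs(lay)
  h <- detect_hinges(p, 2000)
  gs <- tibble::tibble(
    gene_id = sprintf("NM_%02d", 1:10), chrom = "chr1",
    tx_start = seq(0L, 54000L, by = 6000L),
    tx_end = seq(3000L, 57000L, by = 6000L)
  )
  got <- hinge_gene_overlap(gs, h)$has_hinge
  ref <- brute_overlap(gs$tx_start, gs$tx_end, h$span_start, h$span_end)
  expect_equal(got, ref)
})
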