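test_that("overlap fraction uses half-open >=1 bp semantics", {
  q <- tibble::tibble(chrom = "chr1", start = c(100L, 100L), end = c(400L, 400L))
  hit <- tibble::tibble(chrom = "chr1", start = 399L, end = 500L)
  miss <- tibble::tibble(chrom = "chr1", start = 400L, end = 500L)
  expect_equal(overlap_fraction(q, hit)$fraction, 1)
  expect_equal(overlap_fraction(q, miss)$fraction, 0)
})

test_that("overlap fraction agrees with the O(n*m) scan on random instances", {
  withr::local_seed(51)
  for (i in 1:100) {
    nq <- sample(5:120, 1); np <- sample(5:120, 1)
    qs <- sample.int(50000, nq); ps <- sample.int(50000, np)
    q <- tibble::tibble(chrom = "chr1", start = qs, end = qs + sample.int(500, nq, TRUE))
    p <- tibble::tibble(chrom = "chr1", start = ps, end = ps + sample.int(500, np, TRUE))
    got <- overlap_fraction(q, p)
    ref <- brute_overlap(q$start, q$end, p$start, p$end)
    expect_equal(got$n_overlap, sum(ref))
  }
})

test_that("random controls are seeded, sized, and counted per chromosome", {
  n <- c(chr1 = 40L, chr2 = 25L)
  lens <- c(chr1 = 100000L, chr2 = 50000L)
  c1 <- random_control(n, lens, size = 300, seed = 4)
  c2 <- random_control(n, lens, size = 300, seed = 4)
  expect_identical(c1, c2)
  expect_equal(as.vector(table(c1$chrom)[names(n)]), as.vector(n))
  expect_true(all(c1$end - c1$start == 300))
  expect_true(all(c1$end <= lens[c1$chrom]))
  expect_error(random_control(n, c(chr1 = 100L, chr2 = 100L), size = 300),
               "size")
})

test_that("control overlap rate matches the analytic coverage estimate", {
  # a size-s control hits a width-w peak iff its start falls within w + s - 1
  # positions; with peaks sparse the expected fraction is ~ n_peaks*(w+s)/L
  withr::local_seed(52)
  L <- 1e6; w <- 200L; s <- 300L
  ps <- sample.int(L - w, 60)
  peaks <- tibble::tibble(chrom = "chr1", start = ps, end = ps + w)
  ctrl <- random_control(c(chr1 = 5000L), c(chr1 = L), size = s, seed = 11)
  got <- overlap_fraction(ctrl, peaks)$fraction
  expected <- 1 - (1 - (w + s - 1) / L)^60
  expect_equal(got, expected, tolerance = 0.15)
})

test_that("enrichment test detects a planted contrast and is label-antisymmetric", {
  withr::local_seed(53)
  obs <- 0.03 + rnorm(23, 0, 0.005)
  ctrl <- 0.008 + rnorm(23, 0, 0.003)
  e <- enrichment_test(obs, ctrl)
  expect_lt(e$p_value, 0.01)
  expect_gt(e$mean_observed, e$mean_control)
  flip <- enrichment_test(ctrl, obs)
  expect_equal(flip$p_value, e$p_value)
  expect_equal(flip$statistic, -e$statistic)
  expect_equal(enrichment_test(obs, obs)$p_value, 1)
})

test_that("distance profile pools nearest-midpoint distances per a-count bucket", {
  a <- tibble::tibble(chrom = "chr1", start = 995L, end = 1005L)  # mid 1000
  b <- tibble::tibble(chrom = "chr1", start = c(895L, 1495L), end = c(905L, 1505L))
  genes <- tibble::tibble(gene_id = "NM_1", chrom = "chr1",
                          tx_start = 0L, tx_end = 2000L)
  out <- distance_profile(a, b, genes)
  expect_equal(out$a_count, 1)
  expect_equal(out$median_distance, 100)
  # chromosome without b-peaks contributes no distances but is counted
  a2 <- dplyr::bind_rows(a, tibble::tibble(chrom = "chr2", start = 10L, end = 20L))
  genes2 <- dplyr::bind_rows(
    genes, tibble::tibble(gene_id = "NM_2", chrom = "chr2",
                          tx_start = 0L, tx_end = 100L))
  out2 <- distance_profile(a2, b, genes2)
  expect_equal(attr(out2, "n_dropped"), 1)
  expect_equal(out2$n_distances, 1)
})

test_that("distance profile agrees with brute-force nearest neighbours", {
  withr::local_seed(54)
  am <- sort(sample.int(1e5, 400))
  bm <- sort(sample.int(1e5, 300))
  a <- tibble::tibble(chrom = "chr1", start = am, end = am + 1L)
  b <- tibble::tibble(chrom = "chr1", start = bm, end = bm + 1L)
  genes <- tibble::tibble(gene_id = "NM_1", chrom = "chr1",
                          tx_start = 0L, tx_end = 100001L)
  out <- distance_profile(a, b, genes, max_count = 10)
  ref <- brute_nearest(am, bm)
  expect_equal(out$median_distance, median(ref))
  expect_equal(out$n_distances, 400)
})

test_that("denser b-peaks shorten the bucket median monotonically", {
  withr::local_seed(55)
  genes <- tibble::tibble(
    gene_id = sprintf("NM_%02d", 1:60), chrom = "chr1",
    tx_start = seq(0L, 59L) * 10000L, tx_end = seq(1L, 60L) * 10000L
  )
  a <- list(); b <- list()
  for (i in seq_len(60)) {
    cnt <- (i - 1) %/% 6 + 1  # 1..10 a-peaks per gene
    s <- genes$tx_start[i] + sort(sample.int(9000, cnt))
    a[[i]] <- tibble::tibble(chrom = "chr1", start = s, end = s + 10L)
    # b-density rises with the a-count: spacing shrinks
    sb <- genes$tx_start[i] + seq(0L, 9999L, by = as.integer(3000 / cnt))
    b[[i]] <- tibble::tibble(chrom = "chr1", start = sb, end = sb + 10L)
  }
  out <- distance_profile(dplyr::bind_rows(a), dplyr::bind_rows(b), genes)
  expect_equal(out$a_count, 1:10)
  fit <- lm(out$median_distance ~ out$a_count)
  expect_lt(coef(fit)[2], 0)
})

test_that("loop composition conserves span content and classifies frequencies", {
  lay <- chrom_layout(tibble::tibble(start = c(100L, 500L), end = c(200L, 600L)),
                      1000)
  loops <- tibble::tibble(
    chrom_a = "chr1", start_a = c(100L, 300L, 700L), end_a = c(150L, 320L, 720L),
    chrom_b = "chr1", start_b = c(550L, 450L, 900L), end_b = c(600L, 480L, 950L),
    frequency = c(25, 10, 2)
  )
  out <- loop_composition(loops, lay)
  expect_equal(out$class, c("strong", "mid", "transient"))
  expect_equal(out$exon_bp + out$ne_bp, out$span_bp)
  # span [100,600) holds both exons; [300,480) and [700,950) hold none
  expect_equal(out$exon_bp, c(200, 0, 0))
  trans <- loops; trans$chrom_b[1] <- "chr2"
  expect_warning(out2 <- loop_composition(trans, lay), "trans")
  expect_equal(attr(out2, "n_rejected"), 1)
})

test_that("packing ratio covers NE-normalised signal with a power-law fit", {
  regions <- tibble::tibble(
    chrom = "chr1",
    span_start = seq(0L, 9L) * 1000L, span_end = seq(1L, 10L) * 1000L,
    ne_bp = rep(800, 10)
  )
  full <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L)
  out <- packing_ratio(full, regions)
  expect_equal(out$regions$packing_ratio, rep(1000 / 800, 10))
  none <- tibble::tibble(chrom = "chr1", start = integer(), end = integer())
  out0 <- packing_ratio(none, regions)
  expect_equal(out0$regions$packing_ratio, rep(0, 10))
  # signal ~ ne^(1-delta) by construction -> ratio exponent -delta
  withr::local_seed(56)
  ne <- round(10^runif(200, 3, 5))
  starts <- cumsum(c(0, ne[-200] + 100))
  cov_bp <- pmin(round(ne^0.7), ne)
  regions2 <- tibble::tibble(chrom = "chr1", span_start = starts,
                             span_end = starts + ne, ne_bp = ne)
  signal2 <- tibble::tibble(chrom = "chr1", start = starts, end = starts + cov_bp)
  out2 <- packing_ratio(signal2, regions2)
  expect_equal(out2$fit$exponent, -0.3, tolerance = 0.02)
})

test_that("mutation-frequency grouping is ascending, deterministic, near-equal", {
  gt <- tibble::tibble(
    gene_id = sprintf("NM_%03d", 1:100),
    frequency = rep(c(0.1, 0.2, 0.3, 0.4), each = 25),
    has_hinge = rep(c(FALSE, TRUE), 50)
  )
  out <- mutation_frequency_grouping(gt, 4)
  expect_equal(out$n_genes, rep(25L, 4))
  expect_equal(out$mean_frequency, c(0.1, 0.2, 0.3, 0.4))
  # all-equal frequencies give equal means; one gene per group collapses to it
  flat <- gt; flat$frequency <- 0.5
  expect_equal(unique(mutation_frequency_grouping(flat, 5)$mean_frequency), 0.5)
  single <- mutation_frequency_grouping(gt[1:4, ], 4)
  expect_equal(single$mean_frequency, gt$frequency[1:4])
  # hinge probability rising with frequency shows up as a monotone fraction
  withr::local_seed(57)
  gt2 <- tibble::tibble(
    gene_id = sprintf("NM_%04d", 1:2000),
    frequency = runif(2000)
  )
  gt2$has_hinge <- runif(2000) < (0.1 + 0.8 * gt2$frequency)
  out2 <- mutation_frequency_grouping(gt2, 5)
  expect_true(all(diff(out2$hinge_fraction) > 0))
})

test_that("content-distribution comparison wraps a two-sided Mann-Whitney test", {
  withr::local_seed(58)
  a <- rlnorm(80, 10, 1)
  cmp_same <- compare_content_distributions(a, a)
  expect_gt(cmp_same$p_value, 0.9)
  b <- rlnorm(80, 12, 1)
  expect_lt(compare_content_distributions(a, b)$p_value, 0.01)
  expect_equal(cmp_same$p_value, stats::wilcox.test(a, a)$p.value)
})

test_that("class coverage normalises signal by exon and NE bp", {
  lay <- chrom_layout(tibble::tibble(start = 0L, end = 400L), 1000)
  sig <- tibble::tibble(chrom = "chr1", start = c(0L, 500L), end = c(400L, 600L))
  out <- class_coverage(sig, lay)
  expect_equal(out$coverage_per_bp[out$class == "exon"], 1)
  expect_equal(out$coverage_per_bp[out$class == "ne"], 100 / 600)
})
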