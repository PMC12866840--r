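test_that("gamma and C honour the packing-geometry limits and identities", {
  # beta = 0: exons volumetrically distributed, gamma = 2 for any D
  expect_equal(gamma_from(2, 0), 2)
  expect_equal(gamma_from(2.5, 0), 2)
  expect_equal(gamma_from(3, 0), 2)
  # hard-shell polymer limit
  expect_equal(gamma_from(2, 1), 3)
  expect_equal(gamma_from(2.8, 0.7), 1 + 2.8 / 2.1, tolerance = 1e-12)
  expect_equal(C_from(2.8, 0), 1)
  expect_equal(C_from(3, 1), 2 / 3)
  expect_equal(C_from(2.8, 0.7), 0.75)
  expect_error(gamma_from(2, 2), "beta")
  expect_error(gamma_from(1.5, 0), "D")
  # gamma = 1 + 1/C over a (D, beta) grid, machine precision
  grid <- expand.grid(D = seq(2, 3, by = 0.1), beta = seq(0, 1, by = 0.1))
  grid <- grid[grid$D > grid$beta, ]
  expect_equal(gamma_from(grid$D, grid$beta), 1 + 1 / C_from(grid$D, grid$beta),
               tolerance = 1e-14)
  # C is bounded by [1/2, 1] over the full domain (gamma between 2 and 3);
  # the 2/3 lower bound applies on the sub-domain beta <= D/3, with equality
  # at the hard-shell D = 3 endpoint
  Cs <- C_from(grid$D, grid$beta)
  expect_true(all(Cs >= 1 / 2 - 1e-12 & Cs <= 1 + 1e-12))
  sub <- grid$beta <= grid$D / 3
  expect_true(all(Cs[sub] >= 2 / 3 - 1e-12))
})

test_that("volume fraction decays radially and is uniform at D = 3", {
  expect_equal(volume_fraction(10, D = 2.5, phi0 = 0.6, rc = 10), 0.6)
  expect_equal(volume_fraction(40, D = 2.5, phi0 = 0.6, rc = 10),
               0.6 * 4^(-0.5), tolerance = 1e-12)
  r <- c(10, 50, 200)
  expect_equal(volume_fraction(r, D = 3, phi0 = 0.37), rep(0.37, 3))
  expect_true(all(diff(volume_fraction(r, D = 2.6, phi0 = 0.5)) < 0))
  expect_error(volume_fraction(0, D = 2.5), "positive")
})

test_that("mass law integrates the density profile with the same exponent", {
  D <- 2.6; phi0 <- 0.5; rc <- 10
  r_grid <- 10^seq(1.2, 2.5, length.out = 12)
  mass_num <- vapply(r_grid, function(r) {
    stats::integrate(function(x) volume_fraction(x, D, phi0, rc) * 4 * pi * x^2,
                     lower = 1e-6, upper = r, rel.tol = 1e-10)$value
  }, numeric(1))
  slope <- coef(lm(log10(mass_num) ~ log10(r_grid)))[2]
  expect_equal(unname(slope), D, tolerance = 1e-6)
})

test_that("shell content: fractional mode reduces to hard shell at beta = 1", {
  grid <- expand.grid(D = c(2.1, 2.5, 3), r = c(15, 40, 90), dR = c(1, 3))
  hard <- shell_content(grid$r, grid$D, Nc = 1e5, dR = grid$dR, mode = "hard")
  frac <- shell_content(grid$r, grid$D, Nc = 1e5, dR = grid$dR, beta = 1,
                        mode = "fractional")
  expect_equal(frac, hard, tolerance = 1e-14)
  expect_equal(shell_content(10, 3, Nc = 7, dR = 10, A_D = 1, rc = 10),
               3 * 7)  # D * Nc at r = rc, dR = rc
  expect_equal(
    shell_content(10, 2.8, Nc = 5, dR = 10, rc = 10, beta = 0.7,
                  mode = "fractional"),
    4 * 5, tolerance = 1e-12)  # (D/beta) = 4 at r = rc
  expect_error(shell_content(10, 2.8, Nc = 1, dR = 1, beta = 0,
                             mode = "fractional"), "beta")
})

test_that("goldilocks radius inverts the mass law", {
  expect_equal(goldilocks_radius(5e4, D = 2.5, Nc = 5e4), 1)
  expect_equal(goldilocks_radius(4e5, D = 2, Nc = 1e5), 2)
  expect_equal(goldilocks_radius(10, D = 2.8, Nc = 1), 10^(1 / 2.8),
               tolerance = 1e-12)
})

test_that("exon content follows E = Y L^C with the documented limits", {
  # beta = 0 chain limit: exponent 1, prefactor D*k
  L <- 10^seq(3, 6)
  expect_equal(exon_content(L, D = 2.5, beta = 0, k = 1 / 2.5), L)
  # pure power evaluation
  expect_equal(exon_content(1e4, D = 2.8, beta = 0.7, Nc = 1, k = 1 / 2.8),
               (1e4)^0.75, tolerance = 1e-12)
  # strict prefactor reading exposes D/beta
  e1 <- exon_content(1e4, 2.8, 0.7, k = 1)
  e2 <- exon_content(1e4, 2.8, 0.7, k = 1, strict_beta_prefactor = TRUE)
  expect_equal(e2 / e1, 1 / 0.7, tolerance = 1e-12)
  # extended mode: exponent 1 - beta/3; beta = 0 reduces to linear in L
  ext <- exon_content(L, 2.6, beta = 0.9, mode = "extended", phi_gl = 0.3)
  slope <- coef(lm(log10(ext) ~ log10(L)))[2]
  expect_equal(unname(slope), 1 - 0.9 / 3, tolerance = 1e-10)
  ext0 <- exon_content(L, 2.6, beta = 0, mode = "extended", phi_gl = 0.3)
  expect_equal(ext0 / L, rep(3, length(L)))
  expect_error(exon_content(10, 2.6, 0.5, mode = "extended"), "phi_gl")
})

test_that("surface-to-volume decay: E/L falls as L^(-beta/D) at the ideal zone", {
  D <- 2.8; beta <- 0.7
  L <- 10^seq(3, 7, length.out = 9)
  ratio <- exon_content(L, D, beta, Nc = 2e5, k = 0.3) / L
  slope <- coef(lm(log10(ratio) ~ log10(L)))[2]
  expect_equal(unname(slope), -beta / D, tolerance = 1e-10)
})

test_that("tomography genomic-size conversion uses the 15 bp crystalline voxel", {
  expect_equal(chromstem_genomic_size(1, 2, 2.5), 15)
  expect_equal(chromstem_genomic_size(1, 4, 3), 120)
  expect_equal(chromstem_genomic_size(0.5, 100, 2.8), 0.5 * 50^2.8 * 15,
               tolerance = 1e-12)
  # agreement with the mass law when calibrated to the same domain
  D <- 2.7; A <- 0.6; R <- 80
  expect_equal(
    chromstem_genomic_size(A, R, D),
    mass_in_radius(R, D, Nc = 15, A_D = A, rc = 2),
    tolerance = 1e-12
  )
  expect_error(chromstem_genomic_size(1.2, 10, 2.5), "A")
})

test_that("beads-on-a-string worked examples reproduce the printed values", {
  myh1 <- chain_estimate(26000, 200, 5.5)
  expect_equal(myh1$n_nucleosomes, 130)
  expect_equal(myh1$chain_length_nm, 715)
  tg <- chain_estimate(268000, 200, 11)
  expect_equal(tg$n_nucleosomes, 1340)
  expect_equal(tg$chain_length_nm, 14740)
  ttn <- chain_estimate(304000, 200, 11)
  expect_equal(ttn$n_nucleosomes, 1520)
  expect_equal(ttn$chain_length_nm, 16720)
  rbfox1 <- chain_estimate(1527000, 200, 11)
  expect_equal(rbfox1$chain_length_nm / 1000, 84, tolerance = 0.01)
  expect_equal(compression_factor(rbfox1$chain_length_nm, 1000), 84,
               tolerance = 0.01)
  expect_equal(compression_factor(123, 123), 1)
  expect_equal(compression_factor(tg$chain_length_nm, 703), 20.97,
               tolerance = 1e-3)
})
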