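#' Intron-exon scaling exponent from packing-domain geometry
#'
#' The mass-fractal packing-domain model couples the exponent `gamma` of the
#' intron-vs-exon power law `I = E^gamma / p` to the domain fractal dimension
#' `D` and the shell-filling dimension `beta` by
#' `gamma = 1 + D / (D - beta)`. `beta = 0` gives `gamma = 2` for any `D`
#' (exons volumetrically distributed, no shell geometry); `D = 2, beta = 1`
#' gives the upper limit `gamma = 3` (hard shell on a polymer in good
#' solvent).
#'
#' @param D Fractal dimension, `2 <= D <= 3`.
#' @param beta Shell-filling dimension, `0 <= beta <= 1`.
#' @return `gamma_from()`: the exponent `gamma`; `C_from()`: the exon-length
#'   exponent `C = (D - beta)/D` of `E = Y L^C` (bounded between 2/3 and 1
#'   over the valid domain). Both satisfy `gamma = 1 + 1/C`.
#' @export
gamma_from <- function(D, beta) {
  check_D_beta(D, beta)
  1 + D / (D - beta)
}

#' @rdname gamma_from
#' @export
C_from <- function(D, beta) {
  check_D_beta(D, beta)
  (D - beta) / D
}

check_D_beta <- function(D, beta) {
  if (any(D < 2 - 1e-9) || any(D > 3 + 1e-9)) {
    abort("`D` must lie in [2, 3]")
  }
  if (any(beta < 0) || any(beta > 1)) {
    abort("`beta` must lie in [0, 1]")
  }
  if (any(D <= beta)) {
    abort("`D` must exceed `beta`")
  }
  invisible(TRUE)
}

#' Radial chromatin volume fraction of a packing domain
#'
#' `phi(r) = phi0 * (rc / r)^(3 - D)`: the volume fraction decays radially
#' from `phi0` at the chain radius `rc` outward; a uniform globule (`D = 3`)
#' has constant density.
#'
#' @param r Radial distance, nm (`r > 0`).
#' @param D Fractal dimension.
#' @param phi0 Volume fraction at the domain centre.
#' @param rc Chain radius, nm.
#' @return Volume fraction(s) in `[0, phi0]` for `r >= rc`.
#' @export
volume_fraction <- function(r, D, phi0 = 0.5, rc = 10) {
  if (any(r <= 0)) abort("`r` must be positive (the centre value is `phi0` by definition)")
  phi0 * (rc / r)^(3 - D)
}

#' Genomic content within a domain radius
#'
#' `N(r) = Nc * A_D * (r / rc)^D` bp: the mass-scaling law of a packing
#' domain, with `Nc` the chain bp and `A_D` its packing efficiency.
#'
#' @inheritParams volume_fraction
#' @param Nc Basepairs within the chain radius.
#' @param A_D Packing efficiency in `(0, 1]`.
#' @return Basepairs contained within radius `r` (monotone increasing).
#' @export
mass_in_radius <- function(r, D, Nc, A_D = 1, rc = 10) {
  if (any(r < 0)) abort("`r` must be non-negative")
  Nc * A_D * (r / rc)^D
}

#' Genomic content of a domain shell
#'
#' Content of a zone shell of thickness `dR` at radius `r`. The `"hard"` mode
#' differentiates the mass law (a hard shell that the chain cannot cross);
#' the `"fractional"` mode takes the fractional derivative of order `beta`,
#' modelling a chain that wanders in and out of the shell:
#' hard `D * Nc * A_D * (r/rc)^(D-1) * (dR/rc)`;
#' fractional `(D/beta) * Nc * A_D * (r/rc)^(D-beta) * (dR/rc)^beta`.
#' The fractional mode reduces exactly to the hard mode at `beta = 1`.
#'
#' @inheritParams mass_in_radius
#' @param dR Shell thickness, nm (meaningful for `dR << r` in hard mode).
#' @param beta Order of the fractional derivative in `(0, 1]`.
#' @param mode `"hard"` or `"fractional"`.
#' @return Shell content in bp.
#' @export
shell_content <- function(r, D, Nc, dR, A_D = 1, rc = 10, beta = 1,
                          mode = c("hard", "fractional")) {
  mode <- match.arg(mode)
  if (mode == "fractional" && any(beta <= 0)) {
    abort("`beta` must be > 0 in fractional mode (the prefactor diverges at 0)")
  }
  if (mode == "hard") {
    D * Nc * A_D * (r / rc)^(D - 1) * (dR / rc)
  } else {
    (D / beta) * Nc * A_D * (r / rc)^(D - beta) * (dR / rc)^beta
  }
}

#' Goldilocks (ideal-zone) radius of a gene's domain
#'
#' The radius, in units of the chain radius `rc`, at which a domain obeying
#' the mass law contains the whole gene: `Rgl/rc = (L / (Nc * A_D))^(1/D)`.
#'
#' @param L Gene length, bp.
#' @inheritParams mass_in_radius
#' @return `Rgl / rc` (dimensionless).
#' @export
goldilocks_radius <- function(L, D, Nc, A_D = 1) {
  if (any(L <= 0)) abort("`L` must be positive")
  if (any(Nc * A_D <= 0)) abort("`Nc * A_D` must be positive")
  (L / (Nc * A_D))^(1 / D)
}

#' Expected exon content of a gene under the packing model
#'
#' For a domain limited by its ideal zone, the exon content follows
#' `E = Y * L^C` with `C = (D - beta)/D` and prefactor
#' `Y = D * k * (Nc * A_D)^(beta/D) * (dR_gl/rc)^beta`, where `k` is the
#' fraction of shell bp that is exonic. The prefactor is implemented as
#' written, with `k` absorbing the `1/beta` of the fractional derivative
#' (the proportionality constant of the exon-shell relation scales with
#' `beta`); `strict_beta_prefactor = TRUE` exposes the raw `(D/beta) * k`
#' variant instead. The `"extended"` mode covers a domain extending past its
#' ideal zone with matched centre and ideal-zone densities:
#' `E = 3k * phi_gl^(beta/3) * (dR/rc)^beta * L^(1 - beta/3)`.
#'
#' @inheritParams goldilocks_radius
#' @param beta Shell-filling dimension.
#' @param k Exon fraction of shell bp.
#' @param dR_rc Shell thickness over chain radius (dimensionless).
#' @param mode `"ideal"` or `"extended"`.
#' @param phi_gl Volume fraction at the Goldilocks radius; required in
#'   extended mode.
#' @param strict_beta_prefactor Use the `(D/beta) * k` prefactor reading.
#' @return Exon content E in bp.
#' @export
exon_content <- function(L, D, beta, Nc = 1, A_D = 1, k = 1, dR_rc = 1,
                         mode = c("ideal", "extended"), phi_gl = NULL,
                         strict_beta_prefactor = FALSE) {
  mode <- match.arg(mode)
  if (mode == "ideal") {
    pref <- if (strict_beta_prefactor) {
      if (any(beta <= 0)) abort("strict prefactor requires `beta` > 0")
      (D / beta) * k
    } else {
      D * k
    }
    Y <- pref * (Nc * A_D)^(beta / D) * dR_rc^beta
    Y * L^C_from(D, beta)
  } else {
    if (is.null(phi_gl)) abort("extended mode requires `phi_gl`")
    3 * k * phi_gl^(beta / 3) * dR_rc^beta * L^(1 - beta / 3)
  }
}

#' Genomic size of an imaged packing domain
#'
#' Converts an electron-tomography domain (packing efficiency `A`, radius
#' `Rdomain_nm`, fractal dimension `D`) into bp:
#' `A * (Rdomain/2)^D * 15`, taking 15 bp as the DNA content of a fully
#' crystalline 2 nm cube (the brightest possible voxel).
#'
#' @param A Packing efficiency in `(0, 1]`.
#' @param Rdomain_nm Domain radius, nm (`>= 2`).
#' @param D Fractal dimension in `[2, 3]`.
#' @return Estimated genomic size, bp.
#' @export
chromstem_genomic_size <- function(A, Rdomain_nm, D) {
  if (any(A <= 0) || any(A > 1)) abort("`A` must lie in (0, 1]")
  if (any(Rdomain_nm < 2)) abort("`Rdomain_nm` must be >= 2 nm")
  A * (Rdomain_nm / 2)^D * 15
}

#' Beads-on-a-string chain length of a gene
#'
#' Converts a gene body into a fully stretched nucleosome array: a nucleosome
#' is a cylinder of roughly 200 bp, 11 nm diameter and 5.5 nm height, so a
#' gene of `bp` basepairs stacked end-to-end spans
#' `round(bp / bp_per_nucleosome) * extent_nm` nanometres.
#'
#' @param bp Gene length, bp.
#' @param bp_per_nucleosome Basepairs per nucleosome (default 200).
#' @param extent_nm Per-nucleosome extent, nm: 11 (diameter, side-by-side) or
#'   5.5 (height, stacked).
#' @return A tibble with `bp`, `bp_per_nucleosome`, `extent_per_nucleosome`,
#'   `n_nucleosomes`, `chain_length_nm`.
#' @export
chain_estimate <- function(bp, bp_per_nucleosome = 200, extent_nm = 11) {
  if (any(bp <= 0) || any(bp_per_nucleosome <= 0) || any(extent_nm <= 0)) {
    abort("all arguments must be positive")
  }
  n <- round(bp / bp_per_nucleosome)
  tibble(
    bp = bp,
    bp_per_nucleosome = bp_per_nucleosome,
    extent_per_nucleosome = extent_nm,
    n_nucleosomes = n,
    chain_length_nm = n * extent_nm
  )
}

#' Compression factor between chain length and observed extent
#'
#' Ratio of the beads-on-a-string chain length to the experimentally observed
#' spatial extent (for example the TSS-to-TES distance of an active gene).
#'
#' @param chain_length_nm Stretched chain length, nm.
#' @param observed_extent_nm Observed extent, nm (`> 0`).
#' @return Fold-compression (dimensionless).
#' @export
compression_factor <- function(chain_length_nm, observed_extent_nm) {
  if (any(observed_extent_nm <= 0)) abort("`observed_extent_nm` must be positive")
  chain_length_nm / observed_extent_nm
}
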