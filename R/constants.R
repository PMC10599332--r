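#' Physical constants used throughout the package
#'
#' All internal arithmetic uses keV for photon energies, nm for lengths and
#' atoms/nm^3 for number densities; unit conversions happen only at the
#' user-facing boundary.
#'
#' * `hc_kev_nm` -- the product of Planck's constant and the speed of light,
#'   1.239842 keV nm (equivalently 12.39842 keV Angstrom), the single
#'   package-wide conversion between photon energy and wavelength.
#' * `r0_nm` -- the Thomson scattering length (classical electron radius),
#'   2.82e-6 nm. This deliberately keeps the rounded literature value used in
#'   the quantification chain rather than the CODATA 2.8179e-6; it can be
#'   overridden per session via `options(phasetomo.r0_nm = ...)`.
#' * `avogadro` -- Avogadro's constant in 1/mol.
#'
#' @return A named list with elements `hc_kev_nm`, `r0_nm`, `avogadro`.
#' @examples
#' xpct_constants()$hc_kev_nm
#' @export
xpct_constants <- function() {
  list(
    hc_kev_nm = 1.239842,
    r0_nm     = getOption("phasetomo.r0_nm", 2.82e-6),
    avogadro  = 6.02214076e23
  )
}

.hc <- function() 1.239842
.r0 <- function() getOption("phasetomo.r0_nm", 2.82e-6)
.NA <- 6.02214076e23
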