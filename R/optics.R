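#' X-ray wavelength from photon energy
#'
#' Converts photon energy to wavelength via `lambda = hc / E` with
#' hc = 1.239842 keV nm (12.39842 keV Angstrom).
#'
#' @param energy Photon energy in keV. Vectorized.
#' @return Wavelength in nm.
#' @examples
#' energy_wavelength(16)       # 0.07749 nm
#' energy_wavelength(12.39842) # exactly 0.1 nm (1 Angstrom)
#' @export
energy_wavelength <- function(energy) {
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("`energy` must be positive and finite (keV)", call. = FALSE)
  .hc() / energy
}

#' Fresnel number of a parallel-beam imaging geometry
#'
#' `F = px^2 / (z * lambda)` with `px` the effective pixel size and `z` the
#' (effective) sample-to-detector distance. `F << 1` is the holographic
#' regime; `F` is the single parameter governing the Fresnel propagator and
#' the phase-retrieval transfer functions in this package.
#'
#' @param pixel_size Effective pixel size in nm.
#' @param distance Sample-to-detector distance in mm.
#' @param energy Photon energy in keV.
#' @return Dimensionless Fresnel number (per-pixel convention).
#' @examples
#' fresnel_number(650, 149, 16)  # ~0.0366, the holographic regime
#' fresnel_number(650, 29, 16)   # ~0.188, closer to the direct-contrast regime
#' @export
fresnel_number <- function(pixel_size, distance, energy) {
  if (any(pixel_size <= 0) || any(distance <= 0))
    stop("`pixel_size` and `distance` must be positive", call. = FALSE)
  lambda <- energy_wavelength(energy)
  pixel_size^2 / (distance * 1e6 * lambda)
}

#' Imaginary refractive-index part from stain number density
#'
#' `beta = r0 * lambda^2 * rho_a * f2 / (2 * pi)`, the single-element
#' contribution of `rho_a` atoms per nm^3 with imaginary scattering factor
#' `f2` to the optical constant beta of the host material.
#'
#' @param rho_a Atom number density in atoms/nm^3.
#' @param f2 Imaginary atomic scattering factor (dimensionless, >= 0).
#' @param energy Photon energy in keV.
#' @return Dimensionless beta.
#' @seealso [delta_from_number_density()], [mu_from_beta()],
#'   [number_density_from_mu()]
#' @export
beta_from_number_density <- function(rho_a, f2, energy) {
  if (any(rho_a < 0) || any(f2 < 0))
    stop("`rho_a` and `f2` must be non-negative", call. = FALSE)
  lambda <- energy_wavelength(energy)
  .r0() * lambda^2 * rho_a * f2 / (2 * pi)
}

#' Refractive-index decrement from stain number density
#'
#' `delta = r0 * lambda^2 * rho_a * f1 / (2 * pi)`; with `f1 ~ Z + f'` this
#' is the phase-shifting counterpart of [beta_from_number_density()].
#'
#' @inheritParams beta_from_number_density
#' @param f1 Real atomic scattering factor (forward-scattering convention,
#'   `f1 ~ Z + f'`).
#' @return Dimensionless delta.
#' @export
delta_from_number_density <- function(rho_a, f1, energy) {
  if (any(rho_a < 0))
    stop("`rho_a` must be non-negative", call. = FALSE)
  lambda <- energy_wavelength(energy)
  .r0() * lambda^2 * rho_a * f1 / (2 * pi)
}

#' Linear attenuation coefficient from beta
#'
#' `mu = 4 * pi * beta / lambda`, in 1/nm. Multiply by the voxel size in nm
#' to obtain the per-voxel attenuation used in reconstructed histograms.
#'
#' @param beta Imaginary part of the refractive index (>= 0).
#' @param energy Photon energy in keV.
#' @return Attenuation coefficient in 1/nm.
#' @export
mu_from_beta <- function(beta, energy) {
  if (any(beta < 0)) stop("`beta` must be non-negative", call. = FALSE)
  4 * pi * beta / energy_wavelength(energy)
}

#' @rdname mu_from_beta
#' @param mu Linear attenuation coefficient in 1/nm (>= 0).
#' @export
beta_from_mu <- function(mu, energy) {
  if (any(mu < 0)) stop("`mu` must be non-negative", call. = FALSE)
  mu * energy_wavelength(energy) / (4 * pi)
}

#' Stain number density from excess attenuation
#'
#' Inverts the beta -> mu chain for a single stain element:
#' `rho_a = delta_mu / (2 * r0 * lambda * f2)`. This is the core of the
#' stain-quantification workflow: the difference of the attenuation
#' histogram peaks of a stained and an unstained sample, attributed entirely
#' to the stain atoms, yields their number density.
#'
#' @param delta_mu Excess attenuation. In 1/nm, unless `voxel_size` is given,
#'   in which case `delta_mu` is in 1/voxel and divided by `voxel_size` (nm)
#'   first.
#' @param f2 Imaginary atomic scattering factor of the stain element (> 0).
#' @param energy Photon energy in keV.
#' @param voxel_size Optional voxel size in nm for per-voxel input units.
#' @return Number density in atoms/nm^3.
#' @examples
#' # round trip through the forward chain
#' b <- beta_from_number_density(0.01, 3, 13.8)
#' number_density_from_mu(mu_from_beta(b, 13.8), 3, 13.8)  # 0.01
#' @export
number_density_from_mu <- function(delta_mu, f2, energy, voxel_size = NULL) {
  if (any(delta_mu < 0)) stop("`delta_mu` must be non-negative", call. = FALSE)
  if (any(f2 <= 0)) stop("`f2` must be positive", call. = FALSE)
  if (!is.null(voxel_size)) {
    if (any(voxel_size <= 0)) stop("`voxel_size` must be positive", call. = FALSE)
    delta_mu <- delta_mu / voxel_size
  }
  lambda <- energy_wavelength(energy)
  delta_mu / (2 * .r0() * lambda * f2)
}

#' Implied scattering factor diagnostic
#'
#' Back-solves the quantification relation for the `f2` that would make a
#' given excess attenuation and number density mutually consistent:
#' `f2 = delta_mu / (2 * r0 * lambda * rho_a)`. Useful to audit published
#' (delta_mu, rho_a) pairs whose `f2` source is not stated.
#'
#' @inheritParams number_density_from_mu
#' @param rho_a Number density in atoms/nm^3 (> 0).
#' @return The implied dimensionless f2.
#' @export
implied_f2 <- function(delta_mu, rho_a, energy, voxel_size = NULL) {
  if (any(rho_a <= 0)) stop("`rho_a` must be positive", call. = FALSE)
  if (!is.null(voxel_size)) delta_mu <- delta_mu / voxel_size
  lambda <- energy_wavelength(energy)
  delta_mu / (2 * .r0() * lambda * rho_a)
}

#' Mass density from number density
#'
#' `rho = rho_a * A / NA`, converted from atoms/nm^3 to g/cm^3.
#'
#' @param rho_a Number density in atoms/nm^3 (>= 0).
#' @param A Atomic mass in g/mol (> 0).
#' @return Mass density in g/cm^3.
#' @export
mass_density <- function(rho_a, A) {
  if (any(rho_a < 0)) stop("`rho_a` must be non-negative", call. = FALSE)
  if (any(A <= 0)) stop("`A` must be positive", call. = FALSE)
  rho_a * 1e21 * A / .NA
}

#' Mean interatomic distance (Wigner-Seitz radius)
#'
#' Radius of the sphere whose volume is `1 / rho_a`:
#' `d = (3 / (4 * pi * rho_a))^(1/3)`. Reported as the estimated mean
#' distance between stain atoms at a given number density.
#'
#' @param rho_a Number density in atoms/nm^3 (> 0).
#' @return Distance in nm.
#' @examples
#' mean_distance(0.0117)  # ~2.73 nm
#' mean_distance(3 / (4 * pi))  # exactly 1 nm
#' @export
mean_distance <- function(rho_a) {
  if (any(rho_a <= 0)) stop("`rho_a` must be positive", call. = FALSE)
  (3 / (4 * pi * rho_a))^(1 / 3)
}

#' Full density report from excess attenuation
#'
#' Convenience chain: number density, mass density, and mean interatomic
#' distance for a stain element, from a measured excess attenuation.
#'
#' @inheritParams number_density_from_mu
#' @param A Atomic mass in g/mol.
#' @return A list with `number_density` (atoms/nm^3), `mass_density`
#'   (g/cm^3), `mean_distance` (nm).
#' @export
density_result <- function(delta_mu, f2, energy, A, voxel_size = NULL) {
  rho_a <- number_density_from_mu(delta_mu, f2, energy, voxel_size)
  list(
    number_density = rho_a,
    mass_density   = mass_density(rho_a, A),
    mean_distance  = if (rho_a > 0) mean_distance(rho_a) else NA_real_
  )
}
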