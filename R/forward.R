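#' Acquisition geometry for a parallel-beam scan
#'
#' Bundles photon energy, effective pixel size, propagation distance and
#' the projection angles. The Fresnel number is derived via
#' [fresnel_number()]; alternatively it can be given directly and the
#' effective distance is back-computed.
#'
#' @param energy Photon energy in keV.
#' @param pixel_size Effective pixel (= voxel) size in nm.
#' @param distance Sample-to-detector distance in mm (or `NULL` when
#'   `fresnel` is given).
#' @param fresnel Fresnel number (optional; derived from `distance` when
#'   omitted).
#' @param angles Projection angles in degrees, strictly increasing within
#'   `[0, 360)`. Default: `n_projections` uniform angles over 360 degrees.
#' @param n_projections Number of uniform projections over 360 degrees
#'   (ignored when `angles` is given).
#' @return An object of class `acquisition_geometry`.
#' @examples
#' acquisition_geometry(16, 650, distance = 149, n_projections = 180)
#' @export
acquisition_geometry <- function(energy, pixel_size, distance = NULL,
                                 fresnel = NULL, angles = NULL,
                                 n_projections = 180L) {
  if (is.null(angles))
    angles <- seq(0, 360, length.out = n_projections + 1)[seq_len(n_projections)]
  if (any(diff(angles) <= 0) || any(angles < 0) || any(angles >= 360))
    stop("`angles` must be strictly increasing within [0, 360)", call. = FALSE)
  if (is.null(fresnel)) {
    if (is.null(distance)) stop("give either `distance` or `fresnel`", call. = FALSE)
    fresnel <- fresnel_number(pixel_size, distance, energy)
  } else {
    if (fresnel <= 0) stop("`fresnel` must be positive", call. = FALSE)
    if (is.null(distance))
      distance <- pixel_size^2 / (fresnel * energy_wavelength(energy)) / 1e6
  }
  structure(list(energy = energy, pixel_size = pixel_size,
                 distance = distance, fresnel = fresnel,
                 angles = as.numeric(angles),
                 n_projections = length(angles)),
            class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("<acquisition_geometry> %.4g keV, %.0f nm pixels, %.4g mm, F = %.4g, %d angles\n",
              x$energy, x$pixel_size, x$distance, x$fresnel, x$n_projections))
  invisible(x)
}

# per-voxel phase (radians) and attenuation (OD per voxel) cubes of a phantom
phantom_cubes <- function(phantom) {
  lut_d <- c(0, phantom$materials$delta)[phantom$labels + 1L]
  lut_b <- c(0, phantom$materials$beta)[phantom$labels + 1L]
  lambda <- energy_wavelength(phantom$energy)
  vx <- phantom$voxel_size
  list(phase = array(2 * pi * lut_d * vx / lambda, dim = dim(phantom$labels)),
       od = array(4 * pi * lut_b * vx / lambda, dim = dim(phantom$labels)))
}

#' Project a phantom at one rotation angle
#'
#' Line integrals through the phantom about the vertical axis through the
#' in-plane array center, sampled by bilinear interpolation. Returns the
#' projected phase `(2 pi / lambda) * integral(delta dz)` in radians and
#' the optical density `integral(mu dz)` (dimensionless), each as an
#' `(nz x nx)` detector-plane matrix.
#'
#' @param phantom A [make_layer_phantom()] phantom.
#' @param angle Rotation angle in degrees (counter-clockwise viewed from
#'   +z).
#' @return List with matrices `phase` and `absorption`.
#' @export
project <- function(phantom, angle) {
  stopifnot(inherits(phantom, "phantom_volume"))
  cubes <- phantom_cubes(phantom)
  a <- angle * pi / 180
  list(phase = cpp_project_volume(cubes$phase, a),
       absorption = cpp_project_volume(cubes$od, a))
}

# frequency grid in cycles/pixel, FFT (wrap-around) order
fft_freqs <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k < (n + 1) %/% 2, k, k - n) / n
}

fresnel_tf <- function(ny, nx, fresnel) {
  nu2 <- outer(fft_freqs(ny)^2, fft_freqs(nx)^2, `+`)
  exp(-1i * pi * nu2 / fresnel)
}

pad_edge <- function(m, py, px) {
  ri <- c(rep(1, py), seq_len(nrow(m)), rep(nrow(m), py))
  ci <- c(rep(1, px), seq_len(ncol(m)), rep(ncol(m), px))
  m[ri, ci, drop = FALSE]
}

#' Fresnel free-space propagation
#'
#' Applies the Fresnel transfer function
#' `H(nu) = exp(-i pi |nu|^2 / F)` in reduced frequency units
#' (cycles/pixel) to a complex exit wave and returns the detected intensity
#' (squared modulus). The propagator is parameterized solely by the Fresnel
#' number `F`. Boundary handling: the field is edge-replicated to twice its
#' size before the FFT and cropped afterwards (`pad = TRUE`, default);
#' with `pad = FALSE` the transform is periodic and exactly unitary.
#'
#' @param wavefield Complex (or real) 2D matrix, the exit wave.
#' @param fresnel Fresnel number (> 0).
#' @param pad Logical; edge-pad to 2x before transforming.
#' @return Real matrix of intensities.
#' @export
fresnel_propagate <- function(wavefield, fresnel, pad = TRUE) {
  if (!is.finite(fresnel) || fresnel <= 0)
    stop("`fresnel` must be positive and finite", call. = FALSE)
  out <- propagate_field(wavefield, fresnel, pad = pad)
  Re(out * Conj(out))
}

#' @rdname fresnel_propagate
#' @details `propagate_field()` returns the propagated complex field and
#'   accepts negative Fresnel numbers (back-propagation); propagating by
#'   `F` then `-F` with `pad = FALSE` restores the input to machine
#'   precision.
#' @export
propagate_field <- function(wavefield, fresnel, pad = TRUE) {
  if (any(!is.finite(Re(wavefield))) || any(!is.finite(Im(wavefield))))
    stop("`wavefield` must be finite", call. = FALSE)
  if (!is.finite(fresnel) || fresnel == 0)
    stop("`fresnel` must be non-zero and finite", call. = FALSE)
  w <- wavefield
  ny <- nrow(w); nx <- ncol(w)
  if (pad) w <- pad_edge(w, (ny + 1) %/% 2, (nx + 1) %/% 2)
  H <- fresnel_tf(nrow(w), ncol(w), fresnel)
  out <- stats::fft(stats::fft(w) * H, inverse = TRUE) / length(w)
  if (pad) {
    py <- (ny + 1) %/% 2; px <- (nx + 1) %/% 2
    out <- out[py + seq_len(ny), px + seq_len(nx), drop = FALSE]
  }
  out
}

#' Detector parameter set
#'
#' Defaults emulate a synchrotron microtomography acquisition: flat-field
#' level near the full well of a 16-bit camera, a small rate of hot pixels,
#' and static per-column gain errors of a fraction of a percent (the cause
#' of ring artifacts after reconstruction).
#'
#' @param photons_per_pixel Expected photon count per pixel in the flat
#'   field.
#' @param hot_pixel_rate Fraction of pixels overwritten with extreme
#'   values per frame.
#' @param column_gain_sigma Relative standard deviation of the static
#'   per-column gain factors.
#' @param dark_level Mean dark counts per pixel.
#' @param n_flats,n_darks Number of reference frames recorded.
#' @return A named list of class `detector_params`.
#' @export
detector_params <- function(photons_per_pixel = 5e4, hot_pixel_rate = 2e-4,
                            column_gain_sigma = 0.005, dark_level = 100,
                            n_flats = 10L, n_darks = 10L) {
  if (photons_per_pixel <= 0) stop("`photons_per_pixel` must be positive", call. = FALSE)
  structure(list(photons_per_pixel = photons_per_pixel,
                 hot_pixel_rate = hot_pixel_rate,
                 column_gain_sigma = column_gain_sigma,
                 dark_level = dark_level,
                 n_flats = as.integer(n_flats), n_darks = as.integer(n_darks)),
            class = "detector_params")
}

#' Simulate one detector frame
#'
#' Scales an incident intensity pattern to photon counts, applies static
#' per-column gain factors, draws Poisson counts, adds dark counts, and
#' overwrites a seeded subset of pixels with extreme values (hot pixels).
#' Deterministic for a fixed seed. The per-column gains should be drawn
#' once per stack (see [draw_column_gains()]) so that the same pattern is
#' shared by projections and flats.
#'
#' @param intensity 2D matrix of relative intensities (flat field = 1).
#' @param photons_per_pixel Photon count corresponding to intensity 1.
#' @param hot_pixel_rate Fraction of pixels replaced by extreme values;
#'   the number of replaced pixels is exactly
#'   `round(rate * length(intensity))`.
#' @param column_gain_sigma Relative sd of per-column gains (ignored when
#'   `gains` is supplied).
#' @param seed Integer seed.
#' @param gains Optional vector of per-column gain factors.
#' @param dark_level Mean dark counts added to every pixel.
#' @return Matrix of detector counts.
#' @export
simulate_detector <- function(intensity, photons_per_pixel,
                              hot_pixel_rate = 0, column_gain_sigma = 0,
                              seed = 1L, gains = NULL, dark_level = 0) {
  if (photons_per_pixel <= 0) stop("`photons_per_pixel` must be positive", call. = FALSE)
  ny <- nrow(intensity); nx <- ncol(intensity)
  with_seed(seed, {
    if (is.null(gains)) gains <- draw_column_gains(nx, column_gain_sigma, seed)
    lam <- sweep(intensity * photons_per_pixel, 2, gains, `*`) + dark_level
    counts <- matrix(stats::rpois(length(lam), lam), ny, nx)
    n_hot <- round(hot_pixel_rate * length(lam))
    if (n_hot > 0) {
      idx <- sample.int(length(lam), n_hot)
      counts[idx] <- round(photons_per_pixel * stats::runif(n_hot, 2, 5))
      attr(counts, "hot_idx") <- sort(idx)
    }
    counts
  })
}

#' @rdname simulate_detector
#' @param n_cols Number of detector columns.
#' @export
draw_column_gains <- function(n_cols, column_gain_sigma, seed = 1L) {
  with_seed(seed + 1000003L,
            pmax(0.5, stats::rnorm(n_cols, 1, column_gain_sigma)))
}

#' Simulate a full tomographic scan
#'
#' Composes projection, Fresnel propagation and detector simulation per
#' angle: the exit wave of each projection is
#' `t = exp(-OD/2 - i * phase_proj)` (projection approximation; the wave
#' phase is the negative of the projected phase because `n = 1 - delta`),
#' propagated by the geometry's Fresnel number, then detected. Flat and
#' dark frames are generated with the same static column gains.
#'
#' @param phantom A [make_layer_phantom()] phantom.
#' @param geometry An [acquisition_geometry()]. Its pixel size must equal
#'   the phantom voxel size.
#' @param detector A [detector_params()] set.
#' @param seed Integer root seed; all randomness (gains, noise, hot
#'   pixels) derives from it.
#' @param ideal If `TRUE`, skip detector effects and return noiseless
#'   normalized intensities (flats/darks become ideal constants).
#' @return An object of class `hologram_stack`: list with `frames`
#'   (`nz x nx x n_angles` array), `flats`, `darks`, `geometry`, `seed`.
#' @export
simulate_scan <- function(phantom, geometry, detector = detector_params(),
                          seed = 1L, ideal = FALSE) {
  stopifnot(inherits(phantom, "phantom_volume"),
            inherits(geometry, "acquisition_geometry"))
  if (abs(geometry$pixel_size - phantom$voxel_size) > 1e-9)
    stop("geometry pixel size must match phantom voxel size", call. = FALSE)
  cubes <- phantom_cubes(phantom)
  d <- dim(phantom$labels)
  nz <- d[3]; nx <- d[2]
  nang <- geometry$n_projections
  frames <- array(0, dim = c(nz, nx, nang))
  gains <- draw_column_gains(nx, detector$column_gain_sigma, seed)
  for (a in seq_len(nang)) {
    ang <- geometry$angles[a] * pi / 180
    phase <- cpp_project_volume(cubes$phase, ang)
    od <- cpp_project_volume(cubes$od, ang)
    wave <- exp(complex(real = -od / 2, imaginary = -phase))
    holo <- fresnel_propagate(matrix(wave, nz, nx), geometry$fresnel)
    frames[, , a] <- if (ideal) holo else
      simulate_detector(holo, detector$photons_per_pixel,
                        detector$hot_pixel_rate, seed = seed + a,
                        gains = gains, dark_level = detector$dark_level)
  }
  make_ref <- function(k, level, seed0) {
    arr <- array(0, dim = c(nz, nx, k))
    for (i in seq_len(k))
      arr[, , i] <- if (ideal) matrix(level, nz, nx) else
        simulate_detector(matrix(level, nz, nx), detector$photons_per_pixel,
                          0, seed = seed0 + i, gains = gains,
                          dark_level = detector$dark_level)
    arr
  }
  flats <- make_ref(detector$n_flats, 1, seed + 20000L)
  darks <- if (ideal) array(0, dim = c(nz, nx, detector$n_darks)) else {
    arr <- array(0, dim = c(nz, nx, detector$n_darks))
    for (i in seq_len(detector$n_darks))
      arr[, , i] <- with_seed(seed + 30000L + i,
        matrix(stats::rpois(nz * nx, detector$dark_level), nz, nx))
    arr
  }
  structure(list(frames = frames, flats = flats, darks = darks,
                 geometry = geometry, seed = seed,
                 detector = detector, ideal = ideal),
            class = "hologram_stack")
}

#' @export
print.hologram_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<hologram_stack> %d frames of %d x %d px (+%d flats, %d darks), F = %.4g, seed %d\n",
              d[3], d[1], d[2], dim(x$flats)[3], dim(x$darks)[3],
              x$geometry$fresnel, x$seed))
  invisible(x)
}
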