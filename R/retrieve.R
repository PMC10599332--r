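#' Phase-retrieval configuration
#'
#' Parameters of single-distance phase retrieval under the
#' homogeneous-object assumption: a fixed coupling `delta/beta` between
#' phase shift and absorption, the Fresnel number of the acquisition, and
#' the two-band Tikhonov regularization weights of the CTF inversion
#' (`reg_low` below the first maximum of `|sin chi|`, `reg_high` above).
#'
#' @param delta_beta Coupling ratio delta/beta (> 0); the paper-style
#'   per-sample values are of order 5-35.
#' @param fresnel Fresnel number (> 0).
#' @param reg_low,reg_high Regularization weights (>= 0); defaults 1e-3 and
#'   1e-1.
#' @param method `"ctf"` or `"paganin"`.
#' @return An object of class `retrieval_config`.
#' @export
retrieval_config <- function(delta_beta, fresnel, reg_low = 1e-3,
                             reg_high = 1e-1, method = c("ctf", "paganin")) {
  method <- match.arg(method)
  if (delta_beta <= 0) stop("`delta_beta` must be positive", call. = FALSE)
  if (fresnel <= 0) stop("`fresnel` must be positive", call. = FALSE)
  if (reg_low < 0 || reg_high < 0)
    stop("regularization weights must be non-negative", call. = FALSE)
  structure(list(delta_beta = delta_beta, fresnel = fresnel,
                 reg_low = reg_low, reg_high = reg_high, method = method),
            class = "retrieval_config")
}

# chi(nu) = pi |nu|^2 / F on the (padded) FFT grid, plus the two-band
# regularization mask with the band edge at the first maximum of |sin chi|
# (chi = pi/2, i.e. |nu|^2 = F/2)
ctf_grids <- function(ny, nx, fresnel) {
  nu2 <- outer(fft_freqs(ny)^2, fft_freqs(nx)^2, `+`)
  chi <- pi * nu2 / fresnel
  list(chi = chi, low_band = nu2 < fresnel / 2)
}

#' Linearized single-distance CTF phase retrieval
#'
#' Inverts the weak-object contrast transfer function of a normalized
#' in-line hologram under the homogeneous-object assumption. In reduced
#' frequency units with `chi = pi |nu|^2 / F`:
#' `phi_hat = FT[I - 1] / (2 (sin chi + cos chi / (delta/beta)) + reg)`,
#' where `reg` equals `reg_low` below the first maximum of `|sin chi|` and
#' `reg_high` above. The returned map uses the optical-thickness sign
#' convention (positive where material adds phase delay, matching the
#' projected phase `(2 pi/lambda) integral(delta dz)`); its DC value is
#' undefined by the filter and set to zero.
#'
#' @param hologram Normalized intensity frame (background about 1).
#' @param config A [retrieval_config()] with `method = "ctf"`.
#' @param pad Edge-pad to 2x before the FFT (default `TRUE`).
#' @return A `phase_map` matrix (attributes: `units`, `method`).
#' @export
ctf_retrieve <- function(hologram, config, pad = TRUE) {
  stopifnot(inherits(config, "retrieval_config"))
  if (config$method != "ctf") stop("config$method must be 'ctf'", call. = FALSE)
  ny <- nrow(hologram); nx <- ncol(hologram)
  contrast <- hologram - 1
  if (pad) contrast <- pad_edge(contrast, (ny + 1) %/% 2, (nx + 1) %/% 2)
  g <- ctf_grids(nrow(contrast), ncol(contrast), config$fresnel)
  denom <- 2 * (sin(g$chi) + cos(g$chi) / config$delta_beta)
  reg <- ifelse(g$low_band, config$reg_low, config$reg_high)
  filt <- denom / (denom^2 + reg)
  Fc <- stats::fft(contrast) * filt
  phi <- Re(stats::fft(Fc, inverse = TRUE)) / length(Fc)
  if (pad) {
    py <- (ny + 1) %/% 2; px <- (nx + 1) %/% 2
    phi <- phi[py + seq_len(ny), px + seq_len(nx), drop = FALSE]
  }
  out <- -(phi - mean(phi))
  attr(out, "units") <- "phase_radians"
  attr(out, "method") <- "ctf"
  out
}

#' Paganin single-material phase retrieval
#'
#' The single-distance low-pass filter for a homogeneous object,
#' `out = -(1/2) (delta/beta) ln( IFT[ FT[I] / (1 + (delta/beta) pi |nu|^2 / F) ] )`,
#' expressed in reduced units and rescaled to phase radians so that CTF and
#' Paganin outputs feed the same reconstruction path. For weak, slowly
#' varying objects the result matches [ctf_retrieve()].
#'
#' @param intensity Normalized intensity frame (> 0 after flooring).
#' @param config A [retrieval_config()] with `method = "paganin"`.
#' @param pad Edge-pad to 2x before the FFT.
#' @param floor_value Lower clip applied before the logarithm.
#' @return A `phase_map` matrix (optical-thickness sign convention, zero
#'   mean).
#' @export
paganin_retrieve <- function(intensity, config, pad = TRUE,
                             floor_value = 1e-6) {
  stopifnot(inherits(config, "retrieval_config"))
  if (config$method != "paganin")
    stop("config$method must be 'paganin'", call. = FALSE)
  ny <- nrow(intensity); nx <- ncol(intensity)
  x <- intensity
  if (pad) x <- pad_edge(x, (ny + 1) %/% 2, (nx + 1) %/% 2)
  g <- ctf_grids(nrow(x), ncol(x), config$fresnel)
  filt <- 1 / (1 + config$delta_beta * g$chi)
  sm <- Re(stats::fft(stats::fft(x) * filt, inverse = TRUE)) / length(x)
  if (any(!is.finite(sm))) stop("non-finite filtered intensity", call. = FALSE)
  sm <- pmax(sm, floor_value)
  out_full <- -0.5 * config$delta_beta * log(sm)
  if (pad) {
    py <- (ny + 1) %/% 2; px <- (nx + 1) %/% 2
    out_full <- out_full[py + seq_len(ny), px + seq_len(nx), drop = FALSE]
  }
  out <- out_full - mean(out_full)
  attr(out, "units") <- "phase_radians"
  attr(out, "method") <- "paganin"
  out
}

#' Verify / refine the Fresnel number from a hologram
#'
#' The radially averaged power spectrum of a weakly scattering hologram
#' carries the CTF oscillations: minima sit near the CTF zeros
#' `pi |nu|^2 / F = m pi`. The function averages the power spectrum of
#' `I - 1` radially, locates minima near their expected positions (within
#' +/- 20% of `f_initial`), refines each by a parabolic fit, and
#' least-squares fits `nu_m^2 = m F` through the origin.
#'
#' @param hologram Normalized intensity frame with broadband structure; a
#'   3D array of frames may be given, in which case the power spectra are
#'   pooled over frames (the object-spectrum ripple averages out while the
#'   CTF zeros stay fixed, stabilizing the fit).
#' @param f_initial Prior estimate of the Fresnel number.
#' @return The refined Fresnel number. If no minima are detectable the
#'   input `f_initial` is returned with attribute `warning = TRUE`.
#' @export
estimate_fresnel_number <- function(hologram, f_initial) {
  if (f_initial <= 0) stop("`f_initial` must be positive", call. = FALSE)
  frames <- if (length(dim(hologram)) == 3) hologram else
    array(hologram, dim = c(dim(hologram), 1))
  if (stats::sd(frames) < 1e-12) {
    out <- f_initial
    attr(out, "warning") <- TRUE
    return(out)
  }
  ny <- dim(frames)[1]; nx <- dim(frames)[2]
  P <- matrix(0, ny, nx)
  for (k in seq_len(dim(frames)[3])) {
    fr <- frames[, , k]
    P <- P + Mod(stats::fft(fr - mean(fr)))^2
  }
  nu <- sqrt(outer(fft_freqs(ny)^2, fft_freqs(nx)^2, `+`))
  nbin <- max(ny, nx) %/% 2
  bins <- pmin(pmax(ceiling(nu * 2 * nbin), 1), nbin)
  rad <- vapply(seq_len(nbin), function(b) {
    v <- P[bins == b]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  nu_axis <- (seq_len(nbin) - 0.5) / (2 * nbin)
  ok <- is.finite(rad) & rad > 0
  rad <- rad[ok]; nu_axis <- nu_axis[ok]
  lrad <- log(rad)
  # whiten: remove the smooth (object-spectrum) baseline with a running
  # median (reflected at the ends) so the CTF minima are unbiased by the
  # falling power-law envelope
  n <- length(lrad)
  half <- max(3L, round(n / 16))
  lpad <- c(rev(lrad[seq_len(half)]), lrad, rev(lrad[n - seq_len(half) + 1]))
  base <- vapply(seq_len(n), function(i)
    stats::median(lpad[i:(i + 2 * half)]), 0)
  resid <- lrad - base
  # locate one minimum inside [lo, hi] by a quadratic fit through the
  # points of the surrounding dip (handles both sharp and broad minima)
  locate_min <- function(lo, hi) {
    sel <- which(nu_axis >= lo & nu_axis <= hi)
    if (length(sel) < 3) return(NA_real_)
    k <- sel[which.min(resid[sel])]
    pts <- sel[resid[sel] <= resid[k] + 0.7]
    pts <- pts[abs(pts - k) <= max(2, length(sel) %/% 2)]
    if (length(pts) >= 4) {
      fit <- stats::lm(resid[pts] ~ nu_axis[pts] + I(nu_axis[pts]^2))
      a <- stats::coef(fit)[[3]]; b <- stats::coef(fit)[[2]]
      if (is.finite(a) && a > 0) {
        v <- -b / (2 * a)
        if (v >= lo && v <= hi) return(v)
      }
    }
    if (k <= 1 || k >= n) return(nu_axis[k])
    y1 <- resid[k - 1]; y2 <- resid[k]; y3 <- resid[k + 1]
    den <- y1 - 2 * y2 + y3
    frac <- if (den > 0) max(-1, min(1, 0.5 * (y1 - y3) / den)) else 0
    nu_axis[k] + frac * (nu_axis[2] - nu_axis[1])
  }
  # two passes: a coarse pass over the first few minima recenters the
  # search windows, then the full fit uses every detectable order with
  # windows narrow enough that neighboring minima never intrude
  f_cur <- f_initial
  for (pass in 1:2) {
    minima_m <- c(); minima_nu2 <- c()
    m_max <- if (pass == 1) 3L else 40L
    for (m in seq_len(m_max)) {
      w <- if (pass == 1) min(0.3, 0.6 / m) else min(0.15, 0.4 / m)
      lo <- sqrt(m * f_cur * (1 - w)); hi <- min(sqrt(m * f_cur * (1 + w)),
                                                 max(nu_axis))
      if (lo >= max(nu_axis)) break
      v <- locate_min(lo, hi)
      if (is.finite(v)) {
        minima_m <- c(minima_m, m)
        minima_nu2 <- c(minima_nu2, v^2)
      }
    }
    if (length(minima_m) == 0) {
      out <- f_initial
      attr(out, "warning") <- TRUE
      return(out)
    }
    f_cur <- sum(minima_m * minima_nu2) / sum(minima_m^2)
  }
  max(min(f_cur, 1.2 * f_initial), 0.8 * f_initial)
}
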