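#' Atomic scattering-factor tables
#'
#' A `scattering_table` holds tabulated anomalous scattering factors
#' `(E, f1, f2)` for one element in the forward-scattering (Henke)
#' convention, where `f1 ~ Z + f'` and `f2 = f''`. All optical-constant
#' arithmetic involving a specific element interpolates these tables.
#'
#' @param symbol Element symbol, e.g. `"Nd"`.
#' @param Z Atomic number (positive integer).
#' @param A Atomic mass in g/mol.
#' @param energy Tabulated energies in keV, strictly increasing.
#' @param f1,f2 Scattering factors at `energy`; `f2` must be >= 0.
#' @return An object of class `scattering_table`: a list with fields
#'   `symbol`, `Z`, `A` and `rows` (a tibble with columns `energy`, `f1`,
#'   `f2`).
#' @export
scattering_table <- function(symbol, Z, A, energy, f1, f2) {
  if (length(energy) < 2 || any(diff(energy) <= 0))
    stop("`energy` must be strictly increasing with at least 2 rows",
         call. = FALSE)
  if (length(f1) != length(energy) || length(f2) != length(energy))
    stop("`f1`, `f2` must match `energy` in length", call. = FALSE)
  if (any(f2 < 0)) stop("`f2` must be non-negative everywhere", call. = FALSE)
  if (Z <= 0 || Z != round(Z)) stop("`Z` must be a positive integer", call. = FALSE)
  if (A <= 0) stop("`A` must be positive", call. = FALSE)
  structure(
    list(symbol = as.character(symbol), Z = as.integer(Z), A = as.numeric(A),
         rows = tibble::tibble(energy = as.numeric(energy),
                               f1 = as.numeric(f1), f2 = as.numeric(f2))),
    class = "scattering_table"
  )
}

#' @export
print.scattering_table <- function(x, ...) {
  cat(sprintf("<scattering_table> %s (Z = %d, A = %.4f g/mol), %d rows over %.3g-%.3g keV\n",
              x$symbol, x$Z, x$A, nrow(x$rows),
              min(x$rows$energy), max(x$rows$energy)))
  invisible(x)
}

#' Read a scattering-factor table from a text file
#'
#' Native format: whitespace-separated columns `E_keV f1 f2` preceded by a
#' single header line `# symbol Z A`. The Henke `.nff` dialect (three
#' columns with energies in eV and a column-name header line) is also
#' accepted; eV energies are auto-detected by magnitude (first tabulated
#' energy > 1000) and converted to keV. Rows with `f1 = -9999` (the Henke
#' missing-value marker) are dropped.
#'
#' @param path File path.
#' @param symbol,Z,A Element metadata, required only when the file header
#'   does not provide it (`.nff` files).
#' @return A [scattering_table()].
#' @export
read_scattering_table <- function(path, symbol = NULL, Z = NULL, A = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^\\s*#", lines, value = TRUE)
  if (length(hdr) >= 1) {
    parts <- strsplit(trimws(sub("^\\s*#\\s*", "", hdr[[1]])), "\\s+")[[1]]
    if (length(parts) >= 3 && !is.na(suppressWarnings(as.numeric(parts[2])))) {
      symbol <- symbol %||% parts[1]
      Z <- Z %||% as.integer(parts[2])
      A <- A %||% as.numeric(parts[3])
    }
  }
  body <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  # .nff files start with a column-name header such as "E(eV) f1 f2"
  first_fields <- strsplit(trimws(body[[1]]), "\\s+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first_fields)))))
    body <- body[-1]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (ncol(m) < 3) stop("expected three columns: energy f1 f2", call. = FALSE)
  keep <- m[, 2] > -9000
  m <- m[keep, , drop = FALSE]
  e <- m[, 1]
  if (e[1] > 1000) e <- e / 1000  # eV dialect
  if (is.null(symbol) || is.null(Z) || is.null(A))
    stop("element metadata missing: supply `symbol`, `Z`, `A` or a '# symbol Z A' header",
         call. = FALSE)
  scattering_table(symbol, Z, A, e, m[, 2], m[, 3])
}

#' Write a scattering table in the native text format
#'
#' @param table A [scattering_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scattering_table <- function(table, path) {
  stopifnot(inherits(table, "scattering_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %d %.5f", table$symbol, table$Z, table$A), con)
  writeLines(sprintf("%.6f %.6f %.6e", table$rows$energy, table$rows$f1,
                     table$rows$f2), con)
  invisible(path)
}

#' Bundled stain scattering tables
#'
#' Loads one of the scattering-factor tables shipped with the package for
#' the stain elements neodymium, osmium, uranium, and iodine (2-50 keV).
#' These fixtures are synthetic: f2 follows a per-shell absorption-edge
#' model (L/M edge jumps with a power-law decay between edges) and f1 is
#' obtained from f2 by a numerical Kramers-Kronig transform plus the
#' relativistic correction. They reproduce the qualitative magnitude and
#' edge structure of standard tabulations but are not a substitute for
#' measured optical constants; K-edge structure within 2-50 keV is not
#' modeled. See the methods vignette.
#'
#' @param symbol One of `"Nd"`, `"Os"`, `"U"`, `"I"`.
#' @return A [scattering_table()].
#' @examples
#' nd <- stain_table("Nd")
#' delta_beta_ratio(nd, 16)
#' @export
stain_table <- function(symbol = c("Nd", "Os", "U", "I")) {
  symbol <- match.arg(symbol)
  path <- system.file("extdata", "scattering",
                      paste0(tolower(symbol), "_f1f2_synthetic.txt"),
                      package = "phasetomo", mustWork = TRUE)
  read_scattering_table(path)
}

#' Interpolate scattering factors at arbitrary energies
#'
#' Piecewise-linear interpolation between tabulated nodes; exact at nodes;
#' no extrapolation outside the tabulated range.
#'
#' @param table A [scattering_table()].
#' @param energy Energies in keV, all within the tabulated range.
#' @return A tibble with columns `energy`, `f1`, `f2`.
#' @export
interp_scattering <- function(table, energy) {
  stopifnot(inherits(table, "scattering_table"))
  r <- table$rows
  if (any(energy < min(r$energy)) || any(energy > max(r$energy)))
    stop(sprintf("energy outside tabulated range [%.4g, %.4g] keV for %s",
                 min(r$energy), max(r$energy), table$symbol), call. = FALSE)
  tibble::tibble(
    energy = energy,
    f1 = stats::approx(r$energy, r$f1, xout = energy, method = "linear")$y,
    f2 = stats::approx(r$energy, r$f2, xout = energy, method = "linear")$y
  )
}

#' delta/beta ratio of a stain element
#'
#' `(Z + f') / f'' = f1 / f2` at the (interpolated) energy. High values
#' favor phase contrast over absorption: the element shifts the X-ray phase
#' strongly while absorbing comparatively little, which is the regime where
#' propagation-based phase retrieval performs best.
#'
#' @param table A [scattering_table()].
#' @param energy Energies in keV within the tabulated range.
#' @return Dimensionless ratio (vectorized over `energy`).
#' @export
delta_beta_ratio <- function(table, energy) {
  s <- interp_scattering(table, energy)
  if (any(s$f2 == 0)) stop("f2 = 0 at requested energy", call. = FALSE)
  s$f1 / s$f2
}

#' Energy scan of stain optical properties
#'
#' Tabulates `f1`, `f2`, and the delta/beta ratio over an energy grid for
#' one or more elements; the tidy output feeds CSV export and plotting.
#'
#' @param tables A list of [scattering_table()] objects (or one table).
#' @param energies Energies in keV; defaults to the intersection-safe grid
#'   2.5-49.5 keV in 0.25 keV steps.
#' @return A tibble with columns `symbol`, `energy`, `f1`, `f2`,
#'   `delta_beta`.
#' @export
delta_beta_scan <- function(tables, energies = seq(2.5, 49.5, by = 0.25)) {
  if (inherits(tables, "scattering_table")) tables <- list(tables)
  out <- lapply(tables, function(tb) {
    s <- interp_scattering(tb, energies)
    tibble::tibble(symbol = tb$symbol, energy = s$energy,
                   f1 = s$f1, f2 = s$f2, delta_beta = s$f1 / s$f2)
  })
  do.call(rbind, out)
}

#' Optical constants of a stained material at a given number density
#'
#' Computes the (delta, beta) contribution of `rho_a` atoms/nm^3 of a stain
#' element, using the element's interpolated scattering factors.
#'
#' @param table A [scattering_table()].
#' @param energy Photon energy in keV.
#' @param rho_a Number density in atoms/nm^3.
#' @return A list with `delta`, `beta`, `f1`, `f2`, `energy`.
#' @export
stain_optical_constants <- function(table, energy, rho_a) {
  s <- interp_scattering(table, energy)
  list(delta = delta_from_number_density(rho_a, s$f1, energy),
       beta  = beta_from_number_density(rho_a, s$f2, energy),
       f1 = s$f1, f2 = s$f2, energy = energy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
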