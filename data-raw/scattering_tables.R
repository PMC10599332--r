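# Generates the synthetic scattering-factor fixtures bundled under
# inst/extdata/scattering/. Run from the package root:
#   Rscript data-raw/scattering_tables.R
#
# Model: f2(E) is a sum of per-shell terms C_s * (E/E_s)^(-q_s) switched on
# at each absorption edge E_s (effective M edge + L3/L2/L1 with standard
# jump ratios), scaled so that f2 just above L1 matches a literature-scale
# anchor. f1 comes from f2 by a numerical Kramers-Kronig transform plus the
# relativistic correction Z* = Z - (Z/82.5)^2.37. K-shell structure within
# the tabulated 2-50 keV range is deliberately not modeled (see the methods
# vignette); the tables are synthetic stand-ins, not measured data.

elements <- list(
  I  = list(Z = 53, A = 126.90447, E_M = 0.62,  C_M = NA, C_deep = 1.2,
            L3 = 4.557, L2 = 4.852, L1 = 5.188,  anchor = 11.0, f2_25 = 4.0),
  Nd = list(Z = 60, A = 144.242,   E_M = 1.00,  C_M = NA, C_deep = 1.5,
            L3 = 6.208, L2 = 6.722, L1 = 7.126,  anchor = 11.5, f2_25 = 5.5),
  Os = list(Z = 76, A = 190.23,    E_M = 2.20,  C_M = 12, C_deep = 2.0,
            L3 = 10.871, L2 = 12.385, L1 = 12.968, anchor = 10.5, f2_25 = NA),
  U  = list(Z = 92, A = 238.0289,  E_M = 3.65,  C_M = 14, C_deep = 3.5,
            L3 = 17.166, L2 = 20.948, L1 = 21.757, anchor = 9.5,  f2_25 = NA)
)
q_deep <- 1.0; q_M <- 1.0; q_L <- 1.7
jumps <- c(L3 = 2.8, L2 = 1.45, L1 = 1.18)

build_shells <- function(el) {
  # deep baseline (everything below the modeled M group), anchored so that
  # its value at 2 keV equals C_deep; switched on at 1 keV to keep the
  # low-energy tail finite for the Kramers-Kronig transform
  sh <- list(list(E = 1.0, C = el$C_deep * (1 / 2)^(-q_deep), q = q_deep))
  # effective M shell
  C_M <- if (is.na(el$C_M)) el$f2_25 * (2.5 / el$E_M)^q_M else el$C_M
  sh <- c(sh, list(list(E = el$E_M, C = C_M, q = q_M)))
  f2_at <- function(E) sum(vapply(sh, function(s)
    if (E >= s$E) s$C * (E / s$E)^(-s$q) else 0, 0))
  for (nm in c("L3", "L2", "L1")) {
    E_s <- el[[nm]]
    below <- f2_at(E_s)
    sh <- c(sh, list(list(E = E_s, C = (jumps[[nm]] - 1) * below, q = q_L)))
    f2_at <- function(E) sum(vapply(sh, function(s)
      if (E >= s$E) s$C * (E / s$E)^(-s$q) else 0, 0))
  }
  scale <- el$anchor / f2_at(el$L1 * 1.01)
  for (i in seq_along(sh)) sh[[i]]$C <- sh[[i]]$C * scale
  sh
}

f2_model <- function(E, shells) {
  vapply(E, function(e) sum(vapply(shells, function(s)
    if (e >= s$E) s$C * (e / s$E)^(-s$q) else 0, 0)), 0)
}

# Kramers-Kronig: f1(E) = Z* + (2/pi) P int_0^inf eps f2(eps)/(E^2-eps^2) deps
kk_f1 <- function(E_targets, shells, Z) {
  Zstar <- Z - (Z / 82.5)^2.37
  g <- function(eps) eps * f2_model(eps, shells)
  eps_log <- exp(seq(log(0.2), log(5000), length.out = 8000))
  g_log <- g(eps_log)
  vapply(E_targets, function(E) {
    a <- 1.5
    lo <- E / a; hi <- E * a
    # outside the log-symmetric window: plain trapezoid (PV not needed)
    out <- eps_log < lo | eps_log > hi
    integrand <- g_log / (E^2 - eps_log^2)
    integrand[!out] <- 0
    I_out <- sum(diff(eps_log) * (integrand[-1] + integrand[-length(eps_log)]) / 2)
    # inside the window: subtract g(E); the PV weight of the window is zero
    tw <- seq(lo, hi, length.out = 4001)
    gE <- g(E)
    num <- g(tw) - gE
    den <- E^2 - tw^2
    f <- num / den
    sing <- abs(tw - E) < (hi - lo) / 8000
    if (any(sing)) { # replace by the analytic limit -g'(E)/(2E)
      h <- 1e-4 * E
      f[sing] <- -(g(E + h) - g(E - h)) / (2 * h) / (2 * E)
    }
    I_win <- sum(diff(tw) * (f[-1] + f[-length(tw)]) / 2)
    Zstar + (2 / pi) * (I_out + I_win)
  }, 0)
}

grid_for <- function(el) {
  # uniform log grid plus the working energies of interest; linear
  # interpolation between nodes smears the edge jumps over one grid cell,
  # adequate for a synthetic table
  g <- c(exp(seq(log(2), log(50), length.out = 48)), 13.8, 16, 20)
  g <- sort(unique(round(g, 4)))
  g[g >= 2 & g <= 50]
}

dir.create(file.path("inst", "extdata", "scattering"),
           recursive = TRUE, showWarnings = FALSE)
for (sym in names(elements)) {
  el <- elements[[sym]]
  shells <- build_shells(el)
  E <- grid_for(el)
  f2 <- f2_model(E, shells)
  f1 <- kk_f1(E, shells, el$Z)
  stopifnot(all(f2 >= 0), all(diff(E) > 0), all(f1 > 0))
  out <- file.path("inst", "extdata", "scattering",
                   paste0(tolower(sym), "_f1f2_synthetic.txt"))
  con <- file(out, "w")
  writeLines(sprintf("# %s %d %.5f", sym, el$Z, el$A), con)
  writeLines(sprintf("%.4f %.5f %.6e", E, f1, f2), con)
  close(con)
  cat(sprintf("%s: f2(13.8)=%.3f f2(16)=%.3f f2(20)=%.3f f1(16)=%.2f f1/f2(20)=%.1f rows=%d\n",
              sym, f2_model(13.8, shells), f2_model(16, shells),
              f2_model(20, shells), f1[which.min(abs(E - 16))],
              f1[which.min(abs(E - 20))] / f2_model(20, shells), length(E)))
}
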