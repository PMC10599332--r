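test_that("wavelength conversion uses hc = 1.239842 keV nm", {
  expect_equal(energy_wavelength(16), 0.0774901, tolerance = 1e-5)
  expect_equal(energy_wavelength(12.39842), 0.1)  # 1 Angstrom exactly
  expect_equal(energy_wavelength(13.8), 0.0898436, tolerance = 1e-5)
  expect_true(energy_wavelength(16) > 0.0774 && energy_wavelength(16) < 0.0776)
  expect_error(energy_wavelength(0), "positive")
  expect_error(energy_wavelength(-3), "positive")
})

test_that("Fresnel number reproduces the working geometries", {
  expect_equal(fresnel_number(650, 149, 16), 0.0366, tolerance = 0.0001 / 0.0366)
  expect_equal(fresnel_number(650, 29, 16), 0.188, tolerance = 3e-3)
  # limit: vanishing pixel size
  expect_lt(fresnel_number(1e-9, 149, 16), 1e-20)
  expect_error(fresnel_number(-650, 149, 16), "positive")
  expect_error(fresnel_number(650, 0, 16), "positive")
})

test_that("Fresnel number scaling is homogeneous", {
  f0 <- fresnel_number(650, 149, 16)
  expect_equal(fresnel_number(1300, 149, 16), 4 * f0)
  expect_equal(fresnel_number(650, 298, 16), f0 / 2)
})

test_that("beta from number density follows the Thomson-length formula", {
  expect_identical(beta_from_number_density(0, 3, 13.8), 0)
  # direct evaluation: r0 lambda^2 rho f2 / (2 pi)
  lam <- energy_wavelength(13.8)
  expect_equal(beta_from_number_density(0.01, 3, 13.8),
               2.82e-6 * lam^2 * 0.01 * 3 / (2 * pi))
  expect_equal(beta_from_number_density(0.01, 3, 13.8), 1.0868e-10,
               tolerance = 1e-3)
  expect_error(beta_from_number_density(-0.1, 3, 13.8), "non-negative")
})

test_that("mu <-> beta conversions are mutually inverse", {
  expect_identical(mu_from_beta(0, 16), 0)
  expect_equal(mu_from_beta(1e-9, 16), 1.6216e-7, tolerance = 1e-4)
  b <- c(1e-10, 3e-9, 5e-8)
  expect_equal(beta_from_mu(mu_from_beta(b, 16), 16), b)
  expect_error(mu_from_beta(-1e-9, 16), "non-negative")
})

test_that("number density from excess attenuation inverts the chain", {
  expect_identical(number_density_from_mu(0, 3, 13.8), 0)
  expect_equal(number_density_from_mu(2.8077e-7, 3, 13.8), 0.184,
               tolerance = 5e-3)
  # per-voxel overload divides by the voxel size first
  expect_equal(number_density_from_mu(2.8077e-7 * 650, 3, 13.8,
                                      voxel_size = 650),
               number_density_from_mu(2.8077e-7, 3, 13.8))
  expect_error(number_density_from_mu(1e-7, 0, 13.8), "positive")
})

test_that("Eqs. beta -> mu -> density compose to the identity", {
  set.seed(42)
  for (i in 1:25) {
    rho <- runif(1, 0, 1)
    f2 <- runif(1, 1e-3, 100)
    en <- runif(1, 5, 50)
    back <- number_density_from_mu(
      mu_from_beta(beta_from_number_density(rho, f2, en), en), f2, en)
    expect_lt(abs(back - rho) / max(rho, 1e-300), 1e-12)
  }
})

test_that("mass density converts atoms/nm^3 to g/cm^3", {
  expect_identical(mass_density(0, 144.242), 0)
  expect_equal(mass_density(0.0117, 144.242), 2.803e-3, tolerance = 5e-4)
  # dimensional round trip: 1 atom/nm^3 of a hypothetical element with
  # A = NA * 1e-21 g/mol has mass density exactly 1 g/cm^3
  expect_equal(mass_density(1, 6.02214076e23 * 1e-21), 1)
})

test_that("mean distance is the Wigner-Seitz radius", {
  expect_equal(round(mean_distance(0.0117), 2), 2.73)
  expect_equal(round(mean_distance(0.0105), 2), 2.83)
  expect_equal(mean_distance(0.0249), 2.13, tolerance = 0.01 / 2.13)
  expect_equal(mean_distance(3 / (4 * pi)), 1)
  expect_error(mean_distance(0), "positive")
})

test_that("mean distance scales as density^(-1/3) and decreases", {
  rho <- c(0.001, 0.01, 0.1, 1)
  d <- mean_distance(rho)
  expect_true(all(diff(d) < 0))
  expect_equal(mean_distance(8 * 0.02), mean_distance(0.02) / 2)
})

test_that("implied f2 diagnostic exposes the published-pair inconsistency", {
  # the published excess attenuation / number density pair at 13.8 keV
  # implies f'' ~ 47, an order of magnitude above tabulated Nd values
  f2_imp <- implied_f2(1.8250e-4, 0.0117, 13.8, voxel_size = 650)
  expect_equal(f2_imp, 47.4, tolerance = 0.01)
  f2_tab <- interp_scattering(stain_table("Nd"), 13.8)$f2
  expect_gt(f2_imp / f2_tab, 5)
})

test_that("density_result chains density, mass and distance consistently", {
  res <- density_result(1.2e-5, 3.454, 16, 144.242, voxel_size = 650)
  expect_equal(res$mass_density, mass_density(res$number_density, 144.242))
  expect_equal(res$mean_distance, mean_distance(res$number_density))
})
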