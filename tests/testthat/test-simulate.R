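test_that("layer phantom volumes match analytic shell volumes", {
  spec <- tibble::tibble(name = c("shell", "core"),
                         outer_radius = c(0.8, 0.5),
                         delta = c(1e-6, 5e-7), beta = c(3e-8, 2e-8))
  ph <- make_layer_phantom(c(128, 128, 128), spec, 650, 16)
  rmax <- 127 / 2
  v_outer <- 4 / 3 * pi * (0.8 * rmax)^3
  v_inner <- 4 / 3 * pi * (0.5 * rmax)^3
  expect_equal(sum(ph$labels == 2), v_inner, tolerance = 0.02)
  expect_equal(sum(ph$labels == 1), v_outer - v_inner, tolerance = 0.02)
})

test_that("layer radii must decrease strictly inward", {
  bad <- tibble::tibble(name = c("a", "b"), outer_radius = c(0.5, 0.8),
                        delta = c(0, 0), beta = c(0, 0))
  expect_error(make_layer_phantom(c(16, 16, 4), bad, 650), "decreasing")
  bad2 <- tibble::tibble(name = "a", outer_radius = 1.2, delta = 0, beta = 0)
  expect_error(make_layer_phantom(c(16, 16, 4), bad2, 650), "decreasing|\\(0, 1\\]")
})

test_that("staining by number density raises beta by the predicted amount", {
  en <- 16
  un <- quantification_phantom(c(32, 32, 4), en, 0)
  st <- quantification_phantom(c(32, 32, 4), en, 0.012)
  d_beta <- st$materials$beta[2] - un$materials$beta[2]
  f2 <- interp_scattering(stain_table("Nd"), en)$f2
  expect_equal(d_beta, beta_from_number_density(0.012, f2, en))
  # unstained layers untouched
  expect_identical(st$materials$beta[c(1, 3)], un$materials$beta[c(1, 3)])
})

test_that("optically empty phantoms project to zero and yield flat fields", {
  spec <- tibble::tibble(name = "void", outer_radius = 0.7,
                         delta = 0, beta = 0)
  ph <- make_layer_phantom(c(32, 32, 8), spec, 650, 16)
  pr <- project(ph, 33)
  expect_true(all(pr$phase == 0) && all(pr$absorption == 0))
  expect_gt(sum(ph$labels), 0)  # labels present but optically empty
  h <- phantom_hologram(ph, 0.0366)
  expect_equal(max(abs(h$holo - 1)), 0, tolerance = 1e-12)
})

test_that("projection of a uniform cylinder gives the chord-length OD", {
  spec <- tibble::tibble(name = "rod", outer_radius = 50 / 63.5,
                         delta = 0, beta = 1)
  ph <- make_layer_phantom(c(128, 128, 4), spec, 650, 16,
                           geometry = "cylinder")
  mu_vox <- 0.001
  lam <- energy_wavelength(16)
  ph$materials$beta <- mu_vox * lam / (4 * pi * 650)  # mu = 0.001/vox
  pr <- project(ph, 0)
  central <- pr$absorption[1, 64:65]
  expect_equal(mean(central), 0.100, tolerance = 0.02)
})

test_that("projected mass is invariant under rotation angle", {
  ph <- weak_phantom(shape = c(64, 64, 64))
  tots <- vapply(seq(0, 170, by = 17),
                 function(a) sum(project(ph, a)$absorption), 0)
  expect_lt((max(tots) - min(tots)) / mean(tots), 0.005)
})

test_that("Fresnel propagation is unitary and invertible", {
  set.seed(7)
  w <- matrix(complex(real = rnorm(64 * 48), imaginary = rnorm(64 * 48)),
              64, 48)
  I1 <- fresnel_propagate(w, 0.05, pad = FALSE)
  expect_equal(sum(I1), sum(Mod(w)^2), tolerance = 1e-12)
  back <- propagate_field(propagate_field(w, 0.05, pad = FALSE), -0.05,
                          pad = FALSE)
  expect_lt(max(Mod(back - w)), 1e-12)
  # uniform field is propagation invariant
  u <- matrix(1 + 0i, 32, 32)
  expect_equal(fresnel_propagate(u, 0.0366), matrix(1, 32, 32),
               tolerance = 1e-12)
  expect_error(fresnel_propagate(matrix(NaN, 4, 4), 0.1), "finite")
  expect_error(fresnel_propagate(matrix(1, 4, 4), -0.1), "positive")
})

test_that("weak sinusoidal phase gratings show the analytic CTF contrast", {
  n <- 256; a <- 0.01; F <- 0.0366
  for (kcyc in c(24, 40)) {
    x <- matrix(rep(seq_len(n) - 1, each = n), n)
    phi <- a * cos(2 * pi * kcyc * x / n)
    I <- fresnel_propagate(exp(-1i * phi), F, pad = FALSE)
    pred <- abs(2 * a * sin(pi * (kcyc / n)^2 / F))
    expect_equal((max(I) - min(I)) / 2, pred, tolerance = 0.01)
  }
})

test_that("detector model is Poisson-correct, seeded and hot-pixel exact", {
  I <- matrix(1, 50, 50)
  # noiseless limit
  f <- simulate_detector(I * 0.7, 1e8, seed = 1)
  expect_lt(max(abs(f / 1e8 - 0.7) / 0.7), 1e-3)
  # Poisson mean over many pixels within 3 standard errors
  f2 <- simulate_detector(I, 1000, seed = 2)
  se <- sqrt(1000 / length(I))
  expect_lt(abs(mean(f2) - 1000), 3 * se)
  # exact hot-pixel count and determinism
  f3 <- simulate_detector(I, 1000, hot_pixel_rate = 0.01, seed = 3)
  expect_identical(length(attr(f3, "hot_idx")), as.integer(round(0.01 * 2500)))
  f4 <- simulate_detector(I, 1000, hot_pixel_rate = 0.01, seed = 3)
  expect_identical(f3, f4)
  expect_false(identical(f3, simulate_detector(I, 1000,
                                               hot_pixel_rate = 0.01,
                                               seed = 4)))
})

test_that("simulated scans are deterministic and fringe-bearing", {
  ph <- weak_phantom(shape = c(48, 48, 48), scale = 20)
  geom <- acquisition_geometry(16, 650, distance = 149, n_projections = 8)
  det <- detector_params(n_flats = 2, n_darks = 2)
  s1 <- simulate_scan(ph, geom, det, seed = 5)
  s2 <- simulate_scan(ph, geom, det, seed = 5)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$flats, s2$flats)
  # holographic fringes: edge contrast far above the pure-absorption level
  h_holo <- phantom_hologram(ph, 0.0366)
  contact <- exp(-h_holo$od)  # contact-regime (pure absorption) image
  expect_gt(max(abs(h_holo$holo - 1)), 5 * max(abs(contact - 1)))
})

test_that("an optically empty scan is statistically identical to its flats", {
  spec <- tibble::tibble(name = "void", outer_radius = 0.7,
                         delta = 0, beta = 0)
  ph <- make_layer_phantom(c(32, 32, 8), spec, 650, 16)
  geom <- acquisition_geometry(16, 650, distance = 149, n_projections = 4)
  st <- simulate_scan(ph, geom, detector_params(n_flats = 4, n_darks = 2),
                      seed = 9)
  m_frames <- mean(st$frames); m_flats <- mean(st$flats)
  pooled_se <- sd(st$frames) / sqrt(length(st$frames)) +
    sd(st$flats) / sqrt(length(st$flats))
  expect_lt(abs(m_frames - m_flats), 4 * pooled_se)
})

test_that("end-to-end weak-object spectrum follows the transfer model", {
  # noiseless cyclic hologram of a weak homogeneous phantom: the contrast
  # spectrum must equal 2(sin chi + cos chi/(delta/beta)) * (-phase hat)
  ph <- weak_phantom(shape = c(128, 128, 128), scale = 0.3)
  h <- phantom_hologram(ph, 0.0366, pad = FALSE)
  Ihat <- fft(h$holo - mean(h$holo))
  phihat <- fft(-(h$phase - mean(h$phase)))
  nu2 <- outer(phasetomo:::fft_freqs(128)^2, phasetomo:::fft_freqs(128)^2, `+`)
  chi <- pi * nu2 / 0.0366
  pred <- 2 * (sin(chi) + cos(chi) / 35) * phihat
  keep <- Mod(phihat) > max(Mod(phihat)) * 1e-2 & nu2 > 0
  rel <- Mod(Ihat[keep] - pred[keep]) / Mod(pred[keep] + 1e-300)
  expect_lt(median(rel), 0.05)
})
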