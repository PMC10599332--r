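test_that("median phase suppression: identity on constants, kernel checks", {
  m <- matrix(3.7, 20, 20)
  expect_equal(suppress_phase(m, 8), m)
  expect_equal(suppress_phase(m, 5), m)
  expect_error(suppress_phase(m, 1), ">= 2")
  expect_error(suppress_phase(m, 25), "larger")
})

test_that("median filtering removes Fresnel fringes from an absorbing edge", {
  # absorbing half plane at the F = 0.188 working point, where the edge
  # diffraction lobes (~1/sqrt(F) px) fit inside the 8x8 window; at much
  # smaller Fresnel numbers the first lobe is wider than the window and
  # partially survives local averaging
  n <- 256
  od <- matrix(rep(0.2 * (seq_len(n) > n / 2), each = 64), 64, n)
  wave <- matrix(exp(complex(real = -od / 2, imaginary = 0 * od)), 64, n)
  holo <- fresnel_propagate(wave, 0.188)
  prof_pre <- colMeans(holo)
  step_height <- abs(exp(-0.2) - 1)
  overshoot_pre <- max(prof_pre) - 1
  expect_gt(overshoot_pre, 0.05 * step_height)
  filt <- suppress_phase(holo, 8)
  prof_post <- colMeans(filt)
  # no overshoot above the flat side beyond 1% of the step height
  expect_lt(max(prof_post) - 1, 0.01 * step_height)
  expect_gt(min(prof_post), exp(-0.2) - 0.01 * step_height)
})

test_that("salt-and-pepper noise is fully removed below 10% density", {
  set.seed(12)
  clean <- matrix(0.5, 64, 64)
  noisy <- clean
  idx <- sample.int(length(noisy), round(0.08 * length(noisy)))
  noisy[idx] <- rep(c(0, 1), length.out = length(idx))
  expect_equal(suppress_phase(noisy, 5), clean, tolerance = 1e-12)
})

test_that("ROI histograms count, locate peaks, and validate bounds", {
  m <- matrix(0.25, 500, 500)
  h <- roi_histogram(m, c(51, 51, 400, 400), bin_width = 1e-2)
  expect_identical(sum(h$counts), 160000L)
  expect_identical(sum(h$counts > 0), 1L)
  expect_equal(h$peak_value, 0.25, tolerance = 0.01 / 0.25)
  expect_error(roi_histogram(m, c(200, 200, 400, 400)), "bounds")
  expect_error(roi_histogram(m, c(1, 1, 10, 10), bin_width = 0), "positive")
})

test_that("the smoothed-histogram peak finds a Gaussian mode", {
  set.seed(33)
  vals <- matrix(rnorm(160000, mean = 5e-4, sd = 5e-5), 400, 400)
  h <- roi_histogram(vals, c(1, 1, 400, 400), bin_width = 1e-5,
                     smooth_sigma = 2)
  expect_lt(abs(h$peak_value - 5e-4), 2e-5)
})

test_that("peak subtraction recovers constructed offsets and flags sign", {
  m <- matrix(rnorm(10000, 1e-3, 5e-5), 100, 100)
  h1 <- roi_histogram(m, c(1, 1, 100, 100), bin_width = 1e-5)
  h2 <- roi_histogram(m + 2e-4, c(1, 1, 100, 100), bin_width = 1e-5)
  expect_identical(peak_subtract(h1, h1), 0)
  expect_equal(peak_subtract(h2, h1), 2e-4, tolerance = 1e-5 / 2e-4)
  neg <- peak_subtract(h1, h2)
  expect_true(isTRUE(attr(neg, "negative")))
})

make_quant_volume <- function(values, voxel = 650) {
  structure(list(values = values, units = "attenuation_per_voxel",
                 voxel_size = voxel, provenance = list()),
            class = "recon_volume")
}

test_that("quantify_stain validates units and returns zero for identity", {
  set.seed(3)
  v <- make_quant_volume(array(rnorm(32 * 32 * 3, 1e-3, 1e-5), c(32, 32, 3)))
  rep0 <- quantify_stain(v, v, c(5, 5, 20, 20), stain_table("Nd"), 16)
  expect_identical(rep0$delta_mu, 0)
  expect_identical(rep0$density$number_density, 0)
  bad <- v
  bad$units <- "phase_per_voxel"
  expect_error(quantify_stain(v, bad, c(5, 5, 20, 20), stain_table("Nd"), 16),
               "units")
  vx <- v
  vx$voxel_size <- 600
  expect_error(quantify_stain(v, vx, c(5, 5, 20, 20), stain_table("Nd"), 16),
               "voxel")
})

test_that("quant reports are internally consistent and tidy-able", {
  set.seed(4)
  base <- array(rnorm(48 * 48 * 3, 2e-3, 2e-5), c(48, 48, 3))
  st <- make_quant_volume(base + 4e-4)
  un <- make_quant_volume(base)
  rep <- quantify_stain(st, un, c(9, 9, 32, 32), stain_table("Nd"), 16,
                        slab = c(1, 3))
  expect_equal(rep$delta_mu, 4e-4, tolerance = 0.05)
  expect_equal(rep$density$mean_distance,
               mean_distance(rep$density$number_density), tolerance = 1e-9)
  expect_equal(rep$density$mass_density,
               mass_density(rep$density$number_density, 144.242),
               tolerance = 1e-6)
  td <- tidy(rep)
  expect_identical(nrow(td), 1L)
  expect_identical(td$element, "Nd")
  gl <- glance(rep)
  expect_identical(gl$n_roi, rep$histograms$stained$n)
})

test_that("phase suppression preserves absorption histograms", {
  # high-frequency power drops by >= 10x on a fringed hologram while the
  # histogram peak of a pure-absorption image moves by < 1 bin
  ph <- weak_phantom(shape = c(128, 128, 128), scale = 40)
  h <- phantom_hologram(ph, 0.0366)
  hf <- function(m) {
    P <- Mod(fft(m - mean(m)))^2
    nu2 <- outer(phasetomo:::fft_freqs(nrow(m))^2,
                 phasetomo:::fft_freqs(ncol(m))^2, `+`)
    sum(P[nu2 > 0.1^2])
  }
  expect_gt(hf(h$holo) / hf(suppress_phase(h$holo, 8)), 10)
  set.seed(14)
  absim <- matrix(rnorm(96 * 96, 1e-3, 2e-5), 96, 96)
  p0 <- roi_histogram(absim, c(9, 9, 80, 80), bin_width = 1e-5)$peak_value
  p1 <- roi_histogram(suppress_phase(absim, 8), c(9, 9, 80, 80),
                      bin_width = 1e-5)$peak_value
  expect_lte(abs(p1 - p0), 1e-5)
})

test_that("recovered excess attenuation increases with true stain density", {
  # noiseless miniature closed loops at three densities; the band must be
  # wide relative to the 8x8 suppression window, hence 128^2 in-plane
  en <- 16
  geom <- acquisition_geometry(en, 650, distance = 149, n_projections = 180)
  cfg <- pipeline_config(retrieval = list(method = "absorption"),
                         preprocess = list(ring_filter = FALSE, k_mad = 10,
                                           find_axis = FALSE))
  recon_for <- function(rho) {
    ph <- quantification_phantom(c(128, 128, 16), en, rho)
    run_reconstruct(cfg, stack = simulate_scan(ph, geom, seed = 1,
                                               ideal = TRUE))
  }
  un <- recon_for(0)
  roi <- quantification_roi(c(128, 128, 16))
  dmus <- vapply(c(0.006, 0.012, 0.024), function(rho) {
    quantify_stain(recon_for(rho), un, roi, stain_table("Nd"), en,
                   slab = c(1, 16), slab_mode = "average",
                   bin_width = 2e-7, smooth_sigma = "auto")$delta_mu
  }, 0)
  expect_true(all(diff(dmus) > 0))
  expect_equal(dmus[3] / dmus[1], 4, tolerance = 0.25)
})
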