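make_test_stack <- function(seed = 11, nz = 16, nx = 64, n_ang = 24,
                            gain_sigma = 0.02, hot = 0) {
  ph <- weak_phantom(shape = c(nx, nx, nz), scale = 30, seed = seed)
  geom <- acquisition_geometry(16, 650, distance = 149,
                               n_projections = n_ang)
  det <- detector_params(photons_per_pixel = 2e4, hot_pixel_rate = hot,
                         column_gain_sigma = gain_sigma,
                         n_flats = 4, n_darks = 4)
  simulate_scan(ph, geom, det, seed = seed)
}

test_that("flat/dark correction maps flats to one and darks to zero", {
  stack <- make_test_stack()
  flat <- apply(stack$flats, c(1, 2), mean)
  dark <- apply(stack$darks, c(1, 2), mean)
  st2 <- stack
  st2$frames <- array(c(flat, dark), dim = c(dim(flat), 2))
  norm <- flat_dark_correct(st2)
  expect_equal(norm$frames[, , 1], matrix(1, nrow(flat), ncol(flat)),
               tolerance = 1e-12)
  expect_lt(max(norm$frames[, , 2]), 1e-5)  # darks floored just above zero
  expect_identical(norm$correction_log[[1]]$step, "flat_dark_correct")
})

test_that("flat/dark correction removes static column gains", {
  # an optically empty sample isolates the detector signature
  spec <- tibble::tibble(name = "void", outer_radius = 0.7,
                         delta = 0, beta = 0)
  ph <- make_layer_phantom(c(64, 64, 16), spec, 650, 16)
  geom <- acquisition_geometry(16, 650, distance = 149, n_projections = 4)
  det <- detector_params(photons_per_pixel = 2e4, hot_pixel_rate = 0,
                         column_gain_sigma = 0.05, n_flats = 8, n_darks = 4)
  stack <- simulate_scan(ph, geom, det, seed = 17)
  raw_cols <- colMeans(stack$frames[, , 1])
  norm <- flat_dark_correct(stack)
  nrm_cols <- colMeans(norm$frames[, , 1])
  expect_lt(sd(nrm_cols / mean(nrm_cols)), 0.1 * sd(raw_cols / mean(raw_cols)))
  # a flat equal to the dark must error
  bad <- stack
  bad$flats <- bad$darks
  expect_error(flat_dark_correct(bad), "denominator|coincide")
})

test_that("hot-pixel repair finds and replaces isolated spikes", {
  f <- matrix(5, 32, 32)
  expect_identical(repair_hot_pixels(f)$n_repaired, 0L)
  set.seed(21)
  f <- matrix(rnorm(32 * 32, 100, 1), 32, 32)
  g <- f
  g[17, 9] <- 100 * 100
  r <- repair_hot_pixels(g, k_mad = 10)
  expect_identical(r$n_repaired, 1L)
  nb <- g[16:18, 8:10]
  expect_equal(r$frame[17, 9], mean(nb[-5]))
  expect_identical(r$frame[-(17 + 8 * 32)], g[-(17 + 8 * 32)])
})

test_that("injected hot pixels are recovered with high sensitivity", {
  set.seed(31)
  I <- matrix(runif(64 * 64, 0.6, 1), 64, 64)
  f <- simulate_detector(I, 5e4, hot_pixel_rate = 5e-3, seed = 31)
  truth <- attr(f, "hot_idx")
  r <- repair_hot_pixels(f, k_mad = 10)
  changed <- which(as.vector(r$frame != f))
  sens <- length(intersect(changed, truth)) / length(truth)
  fp <- length(setdiff(changed, truth)) / length(f)
  expect_gte(sens, 0.95)
  expect_lte(fp, 0.001)
})

test_that("the rotation axis offset is recovered with sub-pixel accuracy", {
  stack <- make_test_stack(seed = 13, nz = 8, nx = 96, n_ang = 24,
                           gain_sigma = 0)
  norm <- flat_dark_correct(stack)
  expect_lt(abs(find_rotation_axis(norm)), 0.1)
  shifted <- apply_axis_shift(norm, -3.5)  # move the axis off-center
  off <- find_rotation_axis(shifted)
  expect_equal(off, 3.5, tolerance = 0.25 / 3.5)
  # antisymmetry under mirroring the detector
  mirrored <- shifted
  mirrored$frames <- mirrored$frames[, rev(seq_len(dim(norm$frames)[2])), ]
  expect_equal(find_rotation_axis(mirrored), -off, tolerance = 0.1)
  # too little angular coverage errors
  short <- norm
  short$frames <- short$frames[, , 1:6]
  short$geometry$angles <- norm$geometry$angles[1:6]
  expect_error(find_rotation_axis(short), "180")
})

test_that("daubechies filters are orthonormal and match closed forms", {
  h2 <- daubechies_filter(2)
  ref <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  expect_equal(h2, ref, tolerance = 1e-12)
  for (ord in c(1, 8, 25)) {
    h <- daubechies_filter(ord)
    expect_equal(sum(h), sqrt(2), tolerance = 1e-8)
    expect_equal(sum(h^2), 1, tolerance = 1e-7)
  }
  expect_error(daubechies_filter(26), "1..25")
})

test_that("the periodized DWT reconstructs perfectly", {
  set.seed(5)
  x <- matrix(rnorm(64 * 9), 64, 9)
  for (ord in c(2, 25)) {
    h <- daubechies_filter(ord)
    dec <- phasetomo:::dwt_multi(x, h, 3)
    expect_equal(phasetomo:::idwt_multi(dec, h), x, tolerance = 1e-9)
  }
})

test_that("the wavelet-FFT ring filter suppresses stripes, not signal", {
  expect_equal(ring_filter_waveletfft(matrix(0, 32, 64)),
               matrix(0, 32, 64))
  # smooth stripe-free sinogram of a generic (off-center) object passes
  # nearly unchanged; a centered circularly symmetric object would itself
  # look like a stripe field to the filter
  n <- 64; c0 <- (n - 1) / 2
  blob <- 0.01 * exp(-(outer((seq_len(n) - 1 - c0 - 9)^2,
                             (seq_len(n) - 1 - c0 + 6)^2, `+`)) / (2 * 6^2))
  vol <- array(blob, dim = c(n, n, 1))
  angs <- seq(0, 352.5, by = 7.5)
  sino <- t(vapply(angs, function(a)
    phasetomo:::cpp_project_volume(vol, a * pi / 180)[1, ], numeric(n)))
  d <- list(sino = sino, angles = angs)
  # analysis wavelet chosen so its support fits the shortest detail band
  # of this small test sinogram (64 detector pixels)
  sm <- ring_filter_waveletfft(d$sino, wavelet = 8, levels = 2)
  expect_lt(sqrt(mean((sm - d$sino)^2)) / sqrt(mean(d$sino^2)), 0.01)
  # constant single-column offset is a pure stripe: > 90% energy removed
  striped <- d$sino
  striped[, 23] <- striped[, 23] + 0.05
  filt <- ring_filter_waveletfft(striped, wavelet = 8, levels = 2)
  resid <- filt - sm
  expect_lt(sum(resid[, 23]^2), 0.1 * sum(0.05^2 * nrow(d$sino)))
  # the ring metric strictly decreases
  expect_lt(ring_metric(filt), ring_metric(striped))
  # second application changes almost nothing (noiseless idempotency)
  again <- ring_filter_waveletfft(filt, wavelet = 8, levels = 2)
  expect_lt(sqrt(mean((again - filt)^2)) / sqrt(mean(d$sino^2)), 0.001)
  expect_error(ring_filter_waveletfft(d$sino, levels = 0), "positive")
  expect_error(ring_filter_waveletfft(matrix(0, 8, 20), levels = 3),
               "divisible")
})
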