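# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# weak two-shell sphere phantom, max projected phase ~0.05 rad at scale = 1
weak_phantom <- function(shape = c(128, 128, 128), delta_beta = 35,
                         scale = 1, seed = 2) {
  d0 <- c(2e-8, 1e-8) * 0.59 * scale
  spec <- tibble::tibble(name = c("shell", "core"),
                         outer_radius = c(0.45, 0.3),
                         delta = d0, beta = d0 / delta_beta)
  make_layer_phantom(shape, spec, 650, 16, seed = seed)
}

# hologram (noiseless) of a phantom projection at a given Fresnel number
phantom_hologram <- function(phantom, fresnel, angle = 0, pad = TRUE) {
  pr <- project(phantom, angle)
  wave <- exp(complex(real = -pr$absorption / 2, imaginary = -pr$phase))
  nz <- nrow(pr$phase)
  list(holo = fresnel_propagate(matrix(wave, nz, ncol(pr$phase)), fresnel,
                                pad = pad),
       phase = pr$phase, od = pr$absorption)
}

# broadband speckle phantom for Fresnel-number self-calibration
speckle_phantom <- function(shape = c(256, 256, 64), seed = 3) {
  host <- tibble::tibble(name = "host", outer_radius = 0.95,
                         delta = 1e-9, beta = 1e-9 / 35)
  make_layer_phantom(shape, host, 650, 16, geometry = "cylinder",
                     speckle = list(layer = "host", n = 500, radius = 2,
                                    delta = 6e-8, beta = 6e-8 / 35,
                                    name = "grains"),
                     seed = seed)
}

# multi-angle noiseless hologram stack of the speckle phantom
speckle_frames <- function(fresnel, seed = 3, n_ang = 6,
                           shape = c(256, 256, 64)) {
  ph <- speckle_phantom(shape, seed)
  angs <- seq(0, 170, length.out = n_ang)
  arr <- array(0, dim = c(shape[3], shape[2], n_ang))
  for (i in seq_along(angs)) {
    h <- phantom_hologram(ph, fresnel, angs[i])
    arr[, , i] <- h$holo
  }
  arr
}

# uniform attenuating disk sinogram (mu per voxel, radius in voxels)
disk_sinogram <- function(n = 128, radius = 40, mu = 0.002, n_ang = 360) {
  c0 <- (n - 1) / 2
  r2 <- outer((seq_len(n) - 1 - c0)^2, (seq_len(n) - 1 - c0)^2, `+`)
  vol <- array((r2 <= radius^2) * mu, dim = c(n, n, 1))
  angs <- seq(0, 360, length.out = n_ang + 1)[seq_len(n_ang)]
  sino <- t(vapply(angs, function(a)
    phasetomo:::cpp_project_volume(vol, a * pi / 180)[1, ], numeric(n)))
  list(sino = sino, angles = angs, mu = mu, radius = radius, n = n,
       mask = r2)
}
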