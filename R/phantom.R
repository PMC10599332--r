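#' Build a layered phantom volume
#'
#' Constructs a 3D label volume of nested, non-overlapping concentric layers
#' (spherical shells or coaxial cylindrical shells around the rotation axis)
#' with per-layer optical constants `(delta, beta)` at a stated energy.
#' Label 0 is the background (embedding resin, optically empty unless given
#' in `background`). Optionally seeds "cell" speckle — small spheres of a
#' distinct material inside one named layer — to mimic a cell layer and to
#' provide broadband structure for self-calibration tests.
#'
#' @param shape Integer vector `(ny, nx, nz)` of voxel counts.
#' @param layer_spec A data frame (or tibble) with columns `name`,
#'   `outer_radius` (fraction of the maximal in-plane radius, strictly
#'   decreasing, in (0, 1]), `delta`, `beta`. The first row is the
#'   outermost layer; each layer fills the gap down to the next radius, the
#'   last layer fills to the center.
#' @param voxel_size Voxel edge length in nm.
#' @param energy Photon energy in keV at which `(delta, beta)` are stated.
#' @param geometry `"sphere"` (concentric spheres, default) or `"cylinder"`
#'   (invariant along the rotation axis; every z slice is identical, which
#'   is convenient for slab-averaged quantification).
#' @param speckle Optional list with fields `layer` (name), `n` (count),
#'   `radius` (voxels), `delta`, `beta`; spheres are placed uniformly at
#'   random (reproducibly from `seed`) with centers inside the named layer.
#' @param seed Integer seed controlling speckle placement.
#' @return An object of class `phantom_volume`: list with `labels`
#'   (integer array `(ny, nx, nz)`), `voxel_size`, `energy`, `materials`
#'   (tibble: `label`, `name`, `delta`, `beta`).
#' @examples
#' spec <- tibble::tibble(name = c("shell", "core"),
#'                        outer_radius = c(0.9, 0.5),
#'                        delta = c(1e-6, 5e-7), beta = c(3e-8, 2e-8))
#' ph <- make_layer_phantom(c(32, 32, 8), spec, voxel_size = 650, energy = 16)
#' @export
make_layer_phantom <- function(shape, layer_spec, voxel_size, energy = 16,
                               geometry = c("sphere", "cylinder"),
                               speckle = NULL, seed = 1L) {
  geometry <- match.arg(geometry)
  layer_spec <- as.data.frame(layer_spec)
  need <- c("name", "outer_radius", "delta", "beta")
  if (!all(need %in% names(layer_spec)))
    stop("`layer_spec` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  r <- layer_spec$outer_radius
  if (any(r <= 0) || any(r > 1) || any(diff(r) >= 0))
    stop("outer radii must be strictly decreasing fractions in (0, 1]",
         call. = FALSE)
  if (any(layer_spec$delta < 0) || any(layer_spec$beta < 0))
    stop("delta and beta must be non-negative", call. = FALSE)
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2; cz <- (nz - 1) / 2
  rmax <- (min(ny, nx) - 1) / 2
  yy <- (seq_len(ny) - 1) - cy
  xx <- (seq_len(nx) - 1) - cx
  r2_plane <- outer(yy^2, xx^2, `+`)
  labels <- array(0L, dim = c(ny, nx, nz))
  radii <- r * rmax
  for (k in seq_len(nz)) {
    zz2 <- if (geometry == "sphere") ((k - 1) - cz)^2 else 0
    rr <- sqrt(r2_plane + zz2)
    sl <- integer(ny * nx)
    # assign outermost first; successive (smaller) shells overwrite inward,
    # so the innermost listed layer fills to the center
    for (li in seq_along(radii)) sl[rr <= radii[li]] <- li
    labels[, , k] <- sl
  }
  materials <- tibble::tibble(label = seq_along(radii),
                              name = as.character(layer_spec$name),
                              delta = layer_spec$delta,
                              beta = layer_spec$beta)
  if (!is.null(speckle)) {
    host <- match(speckle$layer, materials$name)
    if (is.na(host)) stop("speckle layer not found: ", speckle$layer, call. = FALSE)
    lab_new <- nrow(materials) + 1L
    idx <- which(labels == host, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("speckle host layer is empty", call. = FALSE)
    with_seed(seed, {
      centers <- idx[sample.int(nrow(idx), min(speckle$n, nrow(idx))), ,
                     drop = FALSE]
    })
    rad <- speckle$radius
    for (i in seq_len(nrow(centers))) {
      c0 <- centers[i, ]
      ys <- max(1, c0[1] - rad):min(ny, c0[1] + rad)
      xs <- max(1, c0[2] - rad):min(nx, c0[2] + rad)
      zs <- max(1, c0[3] - rad):min(nz, c0[3] + rad)
      d2 <- outer(outer((ys - c0[1])^2, (xs - c0[2])^2, `+`),
                  (zs - c0[3])^2, `+`)
      sub <- labels[ys, xs, zs]
      sub[d2 <= rad^2 & sub == host] <- lab_new
      labels[ys, xs, zs] <- sub
    }
    materials <- rbind(materials,
                       tibble::tibble(label = lab_new,
                                      name = speckle$name %||% "speckle",
                                      delta = speckle$delta,
                                      beta = speckle$beta))
  }
  structure(list(labels = labels, voxel_size = voxel_size, energy = energy,
                 materials = materials),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<phantom_volume> %d x %d x %d voxels (%.0f nm), %d material(s) @ %.4g keV\n",
              d[1], d[2], d[3], x$voxel_size, nrow(x$materials), x$energy))
  print(x$materials)
  invisible(x)
}

#' Retina-like default phantom
#'
#' Five concentric layers named after the murine-eye structures that
#' heavy-atom stains target (sclera, choroid, rods and cones,
#' nuclear/plexiform layers, ganglion cell layer), with soft-tissue optical
#' constants. Unstained layers have delta/beta = 35; in `stain = "coupling"`
#' mode the stain-targeted layers (sclera, rods and cones, ganglion) are set
#' to delta/beta = 5; in `stain = "density"` mode the same layers instead
#' receive the (delta, beta) increments of `stain_density` atoms/nm^3 of the
#' stain element, computed from its scattering table — the mode used by the
#' quantification closed loop.
#'
#' @param shape `(ny, nx, nz)` voxel counts; default `c(256, 256, 256)`.
#' @param voxel_size Voxel size in nm (default 650).
#' @param energy Photon energy in keV (default 16).
#' @param stain `"none"`, `"coupling"` or `"density"`.
#' @param stain_density Stain atom number density in atoms/nm^3 (used in
#'   `"density"` mode).
#' @param element Stain element symbol for [stain_table()].
#' @param delta_base Refractive-index decrement of the reference tissue
#'   layer (default 9e-7, soft tissue at 16 keV).
#' @param geometry,speckle,seed Passed to [make_layer_phantom()]. By default
#'   the ganglion layer receives cell-like speckle.
#' @return A [make_layer_phantom()] phantom.
#' @export
retina_phantom <- function(shape = c(256, 256, 256), voxel_size = 650,
                           energy = 16,
                           stain = c("none", "coupling", "density"),
                           stain_density = 0.012, element = "Nd",
                           delta_base = 9e-7,
                           geometry = "sphere", speckle = TRUE, seed = 1L) {
  stain <- match.arg(stain)
  layers <- tibble::tibble(
    name = c("sclera", "choroid", "rods_cones", "nuclear_plexiform",
             "ganglion"),
    outer_radius = c(0.92, 0.80, 0.70, 0.58, 0.45),
    dens = c(1.15, 1.05, 1.00, 0.95, 0.90)
  )
  layers$delta <- delta_base * layers$dens
  layers$beta <- layers$delta / 35
  targeted <- layers$name %in% c("sclera", "rods_cones", "ganglion")
  if (stain == "coupling") {
    layers$beta[targeted] <- layers$delta[targeted] / 5
  } else if (stain == "density") {
    oc <- stain_optical_constants(stain_table(element), energy, stain_density)
    layers$delta[targeted] <- layers$delta[targeted] + oc$delta
    layers$beta[targeted] <- layers$beta[targeted] + oc$beta
  }
  spk <- if (isTRUE(speckle))
    list(layer = "ganglion", n = 60, radius = max(2, round(shape[1] / 60)),
         delta = delta_base * 1.3, beta = delta_base * 1.3 / 35,
         name = "ganglion_cells")
  make_layer_phantom(shape, layers[c("name", "outer_radius", "delta", "beta")],
                     voxel_size, energy, geometry = geometry, speckle = spk,
                     seed = seed)
}

# evaluate code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}
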