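#' Write / read hologram stacks as TIFF + JSON sidecar
#'
#' On-disk layout: `frames.tif`, `flats.tif`, `darks.tif` (multi-page,
#' 32-bit) plus `meta.json` with the acquisition geometry, seed and the
#' affine value range of each file. TIFF storage is 32-bit fixed point in
#' `[0, 1]`; values are mapped affinely and the `(min, max)` pair recorded
#' in the sidecar, so the round trip is exact to about 1e-9 of the value
#' range.
#'
#' @param stack A [simulate_scan()] hologram stack.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- list(
    frames = write_tiff_scaled(stack$frames, file.path(dir, "frames.tif")),
    flats  = write_tiff_scaled(stack$flats, file.path(dir, "flats.tif")),
    darks  = write_tiff_scaled(stack$darks, file.path(dir, "darks.tif"))
  )
  g <- stack$geometry
  meta <- list(
    energy_kev = g$energy, pixel_size_nm = g$pixel_size,
    distance_mm = g$distance, fresnel = g$fresnel, angles_deg = g$angles,
    seed = stack$seed, ideal = isTRUE(stack$ideal),
    value_ranges = rng,
    correction_log = stack$correction_log %||% list(),
    package_version = as.character(utils::packageVersion("phasetomo"))
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  geometry <- acquisition_geometry(meta$energy_kev, meta$pixel_size_nm,
                                   distance = meta$distance_mm,
                                   angles = meta$angles_deg)
  rd <- function(name) read_tiff_scaled(file.path(dir, paste0(name, ".tif")),
                                        meta$value_ranges[[name]])
  structure(list(frames = rd("frames"), flats = rd("flats"),
                 darks = rd("darks"), geometry = geometry,
                 seed = meta$seed, ideal = isTRUE(meta$ideal)),
            class = "hologram_stack")
}

write_tiff_scaled <- function(arr, path) {
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(arr)[3]), function(k)
    (arr[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  c(lo, hi)
}

read_tiff_scaled <- function(path, rng) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lo <- rng[1]; hi <- rng[2]
  scale <- if (hi > lo) hi - lo else 1
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * scale + lo
  arr
}

#' Write / read reconstructed volumes
#'
#' Multi-page TIFF (one page per z slice) plus a JSON sidecar holding
#' units, voxel size, the affine value range, and the full provenance
#' block.
#'
#' @param volume A [reconstruct_volume()] result.
#' @param path Base path; `.tif` and `.json` files are derived from it.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "recon_volume"))
  base <- sub("\\.tiff?$", "", path)
  rng <- write_tiff_scaled(volume$values, paste0(base, ".tif"))
  jsonlite::write_json(
    list(units = volume$units, voxel_size_nm = volume$voxel_size,
         value_range = rng, provenance = volume$provenance,
         package_version = as.character(utils::packageVersion("phasetomo"))),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  base <- sub("\\.tiff?$", "", path)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  vals <- read_tiff_scaled(paste0(base, ".tif"), meta$value_range)
  structure(list(values = vals, units = meta$units,
                 voxel_size = meta$voxel_size_nm,
                 provenance = meta$provenance),
            class = "recon_volume")
}
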