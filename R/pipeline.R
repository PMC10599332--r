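#' Pipeline configuration
#'
#' A single structured configuration drives the three entry workflows
#' ([run_simulate()], [run_reconstruct()], [run_quantify()]). It
#' round-trips through YAML unchanged and every run logs its effective
#' configuration next to its outputs, so any artifact can be re-derived
#' from config + seed.
#'
#' @param ... Named per-stage sections overriding the defaults: `phantom`,
#'   `geometry`, `detector`, `preprocess`, `retrieval`, `reconstruct`,
#'   `quantify`, `paths`, plus a root `seed`.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    phantom = list(shape = c(128L, 128L, 16L), voxel_size = 650,
                   stain = "none", stain_density = 0.012, element = "Nd",
                   geometry = "sphere", speckle = TRUE),
    geometry = list(energy = 16, distance = 149, n_projections = 180L),
    detector = list(photons_per_pixel = 5e4, hot_pixel_rate = 2e-4,
                    column_gain_sigma = 0.005, dark_level = 100,
                    n_flats = 10L, n_darks = 10L),
    preprocess = list(k_mad = 10, ring_filter = TRUE, wavelet = 25L,
                      levels = 4L, sigma = 2.4, find_axis = TRUE),
    retrieval = list(method = "none", delta_beta = 35,
                     reg_low = 1e-3, reg_high = 1e-1,
                     suppress_kernel = 8L),
    quantify = list(roi = NULL, slab = NULL, bin_width = 1e-5,
                    smooth_sigma = 2),
    paths = list()
  )
  override <- list(...)
  cfg <- utils::modifyList(defaults, override)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_require <- function(cfg, keys) {
  for (k in keys) {
    v <- cfg
    for (part in strsplit(k, ".", fixed = TRUE)[[1]]) {
      v <- v[[part]]
      if (is.null(v)) stop(sprintf("missing required config key: %s", k),
                           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Run the simulation workflow
#'
#' Builds the configured phantom, simulates the scan, and (optionally)
#' writes the hologram stack + metadata sidecar to
#' `config$paths$stack_dir`.
#'
#' @param config A [pipeline_config()].
#' @return The `hologram_stack`, invisibly when written to disk.
#' @export
run_simulate <- function(config = pipeline_config()) {
  config_require(config, c("seed", "phantom.shape", "geometry.energy"))
  ph_cfg <- config$phantom
  phantom <- retina_phantom(
    shape = ph_cfg$shape, voxel_size = ph_cfg$voxel_size,
    energy = config$geometry$energy,
    stain = ph_cfg$stain, stain_density = ph_cfg$stain_density,
    element = ph_cfg$element, geometry = ph_cfg$geometry,
    speckle = isTRUE(ph_cfg$speckle), seed = config$seed)
  geom <- acquisition_geometry(config$geometry$energy, ph_cfg$voxel_size,
                               distance = config$geometry$distance,
                               fresnel = config$geometry$fresnel,
                               n_projections = config$geometry$n_projections)
  det <- do.call(detector_params, config$detector)
  stack <- simulate_scan(phantom, geom, det, seed = config$seed)
  if (!is.null(config$paths$stack_dir)) {
    write_stack(stack, config$paths$stack_dir)
    write_pipeline_config(config,
                          file.path(config$paths$stack_dir, "config.yaml"))
    return(invisible(stack))
  }
  stack
}

#' Run the reconstruction workflow
#'
#' Projection-domain corrections (flat/dark, hot pixels, rotation axis),
#' the selected projection transform — CTF or Paganin phase retrieval,
#' plain `-log` attenuation, or median-filter phase suppression + `-log`
#' (`method = "absorption"`) — then per-slice ring filtering and Ram-Lak
#' filtered backprojection.
#'
#' @param config A [pipeline_config()]; `retrieval$method` is one of
#'   `"ctf"`, `"paganin"`, `"none"` (plain attenuation) or
#'   `"absorption"` (median-filter phase suppression, the quantification
#'   path).
#' @param stack Optional in-memory `hologram_stack`; read from
#'   `config$paths$stack_dir` when omitted.
#' @return A [reconstruct_volume()] result (written to
#'   `config$paths$volume` when set).
#' @export
run_reconstruct <- function(config = pipeline_config(), stack = NULL) {
  if (is.null(stack)) {
    config_require(config, "paths.stack_dir")
    stack <- read_stack(config$paths$stack_dir)
  }
  geom <- stack$geometry
  norm <- flat_dark_correct(stack)
  norm <- repair_hot_pixels_stack(norm, k_mad = config$preprocess$k_mad)
  offset <- if (isTRUE(config$preprocess$find_axis))
    tryCatch(find_rotation_axis(norm), error = function(e) 0) else 0
  norm <- apply_axis_shift(norm, offset)
  method <- config$retrieval$method
  frames <- norm$frames
  units <- "attenuation_per_voxel"
  if (method %in% c("ctf", "paganin")) {
    rc <- retrieval_config(config$retrieval$delta_beta, geom$fresnel,
                           config$retrieval$reg_low,
                           config$retrieval$reg_high, method = method)
    for (a in seq_len(dim(frames)[3]))
      frames[, , a] <- if (method == "ctf")
        ctf_retrieve(frames[, , a], rc) else paganin_retrieve(frames[, , a], rc)
    units <- "phase_per_voxel"
  } else if (method == "absorption") {
    for (a in seq_len(dim(frames)[3]))
      frames[, , a] <- -log(pmax(
        suppress_phase(frames[, , a], config$retrieval$suppress_kernel),
        1e-6))
  } else if (method == "none") {
    for (a in seq_len(dim(frames)[3]))
      frames[, , a] <- -log(pmax(frames[, , a], 1e-6))
  } else stop("unknown retrieval method: ", method, call. = FALSE)
  vol <- reconstruct_volume(
    frames, geom$angles, axis_offset = 0, units = units,
    voxel_size = geom$pixel_size,
    ring_filter = isTRUE(config$preprocess$ring_filter),
    wavelet = config$preprocess$wavelet, levels = config$preprocess$levels,
    sigma = config$preprocess$sigma)
  vol$provenance <- c(vol$provenance,
                      list(method = method, axis_offset_found = offset,
                           seed = stack$seed,
                           energy = geom$energy, fresnel = geom$fresnel))
  if (!is.null(config$paths$volume)) write_volume(vol, config$paths$volume)
  vol
}

#' Run the stain-quantification workflow
#'
#' Applies [quantify_stain()] to a stained/unstained volume pair and
#' optionally writes a JSON report plus per-input histogram CSVs.
#'
#' @param config A [pipeline_config()] whose `quantify` section must
#'   contain `roi`; `phantom$element` names the stain.
#' @param stained,unstained `recon_volume` objects (read from
#'   `config$paths$stained_volume` / `unstained_volume` when omitted).
#' @return A `quant_report`.
#' @export
run_quantify <- function(config = pipeline_config(), stained = NULL,
                         unstained = NULL) {
  if (is.null(stained)) {
    config_require(config, "paths.stained_volume")
    stained <- read_volume(config$paths$stained_volume)
  }
  if (is.null(unstained)) {
    config_require(config, "paths.unstained_volume")
    unstained <- read_volume(config$paths$unstained_volume)
  }
  config_require(config, c("quantify.roi", "geometry.energy"))
  rep <- quantify_stain(stained, unstained, config$quantify$roi,
                        stain_table(config$phantom$element),
                        config$geometry$energy,
                        slab = config$quantify$slab,
                        bin_width = config$quantify$bin_width,
                        smooth_sigma = config$quantify$smooth_sigma)
  if (!is.null(config$paths$report)) {
    jsonlite::write_json(quant_report_json(rep), config$paths$report,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    base <- sub("\\.json$", "", config$paths$report)
    for (side in c("stained", "unstained")) {
      h <- rep$histograms[[side]]
      utils::write.csv(
        data.frame(bin_center = h$bin_edges[-length(h$bin_edges)] +
                     diff(h$bin_edges) / 2, count = h$counts),
        paste0(base, "_", side, "_hist.csv"), row.names = FALSE)
    }
  }
  rep
}

quant_report_json <- function(rep) {
  list(element = rep$element, energy_kev = rep$energy,
       voxel_size_nm = rep$voxel_size,
       delta_mu_per_voxel = rep$delta_mu, negative = rep$negative,
       f2_used = rep$f2_used, f2_source = rep$f2_source,
       number_density_per_nm3 = rep$density$number_density,
       mass_density_g_cm3 = rep$density$mass_density,
       mean_distance_nm = rep$density$mean_distance,
       roi = rep$roi, slab = rep$slab,
       package_version = as.character(utils::packageVersion("phasetomo")))
}
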