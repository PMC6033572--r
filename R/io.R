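#' Read a simulation configuration from YAML
#'
#' Recognized blocks: `solver` (cell_size_um, dims, dt_fs, n_iterations,
#' pml{thickness, order, target_amplitude}), `optics` (f1_mm, f2_mm, Ra_mm,
#' mfd_um, band_nm, lambda0_nm, n_k, polarization), `detector`
#' (eta | target_snr_db, seed, window, n_k).
#'
#' @param path YAML file path.
#' @return List with `grid` ([grid_spec()]), `optics` ([optical_system()]),
#'   `detector` ([detector_model()]), and the raw config.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(raw = cfg)
  if (!is.null(cfg$solver)) {
    s <- cfg$solver
    pml <- s$pml %||% list()
    out$grid <- grid_spec(
      cell_size = s$cell_size_um,
      dims = unlist(s$dims),
      pml_thickness = pml$thickness %||% 10,
      pml_order = pml$order %||% 3,
      pml_target_amplitude = pml$target_amplitude %||% 1e-4,
      background_index = s$background_index %||% 1)
  }
  if (!is.null(cfg$optics)) {
    o <- cfg$optics
    out$optics <- optical_system(
      f1_mm = o$f1_mm %||% 25, f2_mm = o$f2_mm %||% 36,
      Ra_mm = o$Ra_mm %||% 3.5, mfd_um = o$mfd_um %||% 9.2,
      band_nm = unlist(o$band_nm %||% c(1180, 1420)),
      lambda0_nm = o$lambda0_nm %||% 1300, n_k = o$n_k %||% 2048)
  }
  if (!is.null(cfg$detector)) {
    d <- cfg$detector
    out$detector <- detector_model(
      eta = d$eta %||% 1, window = d$window %||% "hann",
      seed = d$seed %||% 1L)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a B-scan image as TIFF (dB SNR scale)
#'
#' @param image_db Numeric matrix in dB.
#' @param path Output file.
#' @param range dB range mapped to [0, 1].
#' @export
write_bscan_tiff <- function(image_db, path, range = c(0, 60)) {
  img <- (image_db - range[1]) / (range[2] - range[1])
  img <- pmin(1, pmax(0, img))
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  invisible(path)
}

#' Serialize a scatterer design to JSON
#'
#' @param design A [scatterer_design()].
#' @param path Output file.
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(list(params = design$params,
                            cell_size = design$cell_size,
                            bounds = design$bounds),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scatterer design from JSON
#'
#' @param path JSON file written by [write_design_json()].
#' @return A [scatterer_design()].
#' @export
read_design_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scatterer_design(x$params, x$cell_size, x$bounds)
}
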