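#' One-dimensional OCT coupling spectra
#'
#' Runs the axial (1D) reduction of the imaging model three times on the
#' same grid - sample, homogeneous (illumination), and mirror (reference) -
#' and evaluates the scalar fiber coupling at a detection plane for every
#' requested wavenumber. The mirror is a perfect electric conductor plane at
#' `mirror_z`.
#'
#' @param n_profile Refractive index along z (length nz), the sample.
#' @param cell_size Cell size (um).
#' @param wavenumbers Vacuum wavenumbers (rad/um).
#' @param mirror_z 1-based z index of the reference mirror plane.
#' @param pml_thickness Absorber cells at each z end.
#' @param source_z,detector_z Plane indices; defaults just inside the
#'   absorber.
#' @param W Source envelope width (fs).
#' @param background_index Index of the homogeneous space above the sample.
#' @param run_time_factor Settling margin for the run length.
#' @return A [coupling_spectrum()].
#' @export
oct_coupling_1d <- function(n_profile, cell_size, wavenumbers, mirror_z,
                            pml_thickness = 10, source_z = NULL,
                            detector_z = NULL, W = 10,
                            background_index = 1.42,
                            run_time_factor = 2.5) {
  nz <- length(n_profile)
  g <- grid_spec(cell_size, c(1, 1, nz), pml_thickness = pml_thickness,
                 background_index = background_index)
  if (is.null(source_z)) source_z <- pml_thickness + 3L
  if (is.null(detector_z)) detector_z <- pml_thickness + 5L
  k0 <- mean(range(wavenumbers))
  src <- source_spec(source_z, matrix(1 + 0i, 1, 1), matrix(0i, 1, 1),
                     k0 = k0, W = W, t0 = 2.5 * W)
  dt <- 0.45 * stability_limit(g, n_min = 1)
  v <- C_UM_FS / max(n_profile)
  t_total <- src$t0 + run_time_factor * (2 * nz * cell_size / v + 6 * W)
  nsteps <- ceiling(t_total / dt)
  run <- function(nvec, pec_z = NULL) {
    pec <- NULL
    if (!is.null(pec_z)) {
      pec <- array(0, g$dims)
      pec[1, 1, pec_z] <- 1
    }
    out <- pstd_simulate(g, n = array(nvec, g$dims), source = src,
                         nsteps = nsteps, dt = dt,
                         wavenumbers = wavenumbers, plane_z = detector_z,
                         pec = pec)
    list(ex = out$plane_Ex, ey = out$plane_Ey)
  }
  homog <- rep(background_index, nz)
  ill <- run(homog)
  tot <- run(n_profile)
  ref <- run(homog, pec_z = mirror_z)
  nk <- length(wavenumbers)
  a_tot <- a_ref <- a_ill <- complex(length.out = nk)
  for (k in seq_len(nk)) {
    w_ill <- list(ex = ill$ex[, , k, drop = TRUE],
                  ey = ill$ey[, , k, drop = TRUE])
    w_ill <- lapply(w_ill, function(m) matrix(m, 1, 1))
    grab <- function(fld) lapply(list(ex = fld$ex[, , k, drop = TRUE],
                                      ey = fld$ey[, , k, drop = TRUE]),
                                 function(m) matrix(m, 1, 1))
    a_tot[k] <- overlap_coupling(w_ill, grab(tot), cell_size)
    a_ref[k] <- overlap_coupling(w_ill, grab(ref), cell_size)
    a_ill[k] <- overlap_coupling(w_ill, grab(ill), cell_size)
  }
  coupling_spectrum(wavenumbers, a_tot, a_ref, a_ill)
}

#' Optical depth of a sample feature relative to the reference mirror
#'
#' One-way optical path difference between a feature plane and the
#' reference-mirror plane (sum of n dz), the depth at which the
#' reconstructed A-scan peak of that feature appears.
#'
#' @param n_profile Refractive index along z.
#' @param cell_size Cell size (um).
#' @param feature_z,mirror_z 1-based plane indices.
#' @return Optical path difference (um).
#' @export
optical_depth <- function(n_profile, cell_size, feature_z, mirror_z) {
  lo <- min(feature_z, mirror_z); hi <- max(feature_z, mirror_z)
  s <- sum(n_profile[lo:(hi - 1)]) * cell_size
  if (feature_z >= mirror_z) s else -s
}
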