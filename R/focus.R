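#' Optical system specification
#'
#' Fiber-coupled 4f illumination/detection optics: a single-mode fiber whose
#' Gaussian mode is collimated by L1 (focal length `f1`), truncated by an
#' aperture of radius `Ra` at the common focal plane, and focused by L2
#' (`f2`) into the sample. The numerical aperture is `Ra / f2`.
#'
#' @param f1_mm,f2_mm Focal lengths (mm).
#' @param Ra_mm Aperture radius (mm).
#' @param mfd_um Fiber mode field diameter (1/e^2 intensity diameter, um).
#' @param band_nm Vacuum wavelength interval c(min, max), nm.
#' @param lambda0_nm Central vacuum wavelength, nm.
#' @param n_k Number of spectral samples (uniform in wavenumber).
#' @param polarization Transverse Jones vector c(px, py); normalized.
#' @return An object of class `optical_system`.
#' @export
optical_system <- function(f1_mm = 25, f2_mm = 36, Ra_mm = 3.5,
                           mfd_um = 9.2, band_nm = c(1180, 1420),
                           lambda0_nm = 1300, n_k = 2048,
                           polarization = c(1, 0)) {
  stopifnot(f1_mm > 0, f2_mm > 0, Ra_mm > 0, mfd_um > 0,
            band_nm[1] < lambda0_nm, lambda0_nm < band_nm[2],
            length(polarization) == 2)
  pol <- polarization / sqrt(sum(Mod(polarization)^2))
  structure(list(f1 = f1_mm * 1e3, f2 = f2_mm * 1e3, Ra = Ra_mm * 1e3,
                 mfd = mfd_um, band_nm = band_nm, lambda0_nm = lambda0_nm,
                 n_k = as.integer(n_k), polarization = pol,
                 NA_obj = Ra_mm / f2_mm),
            class = "optical_system")
}

#' Uniform wavenumber sampling of the system band
#'
#' @param system An [optical_system()].
#' @param n_k Number of samples (default: the system's).
#' @return Vacuum wavenumbers (rad/um), increasing.
#' @export
band_wavenumbers <- function(system, n_k = system$n_k) {
  seq(2 * pi / (system$band_nm[2] / 1e3), 2 * pi / (system$band_nm[1] / 1e3),
      length.out = n_k)
}

#' Gaussian fiber mode profile
#'
#' Weakly-guiding approximation: a unit-energy Gaussian whose 1/e^2
#' intensity diameter equals the mode field diameter.
#'
#' @param mfd Mode field diameter (um).
#' @return A function of radius (um) returning the amplitude; its squared
#'   integral over the transverse plane is 1.
#' @export
fiber_mode <- function(mfd) {
  stopifnot(mfd > 0)
  w0 <- mfd / 2
  function(r) sqrt(2 / pi) / w0 * exp(-(r / w0)^2)
}

#' Field at the aperture plane of the 4f system
#'
#' Fourier-optics image of the fiber mode at the common focal plane of L1
#' and L2: a Gaussian of amplitude waist `w_pupil = 2 f1 / (k w0)`
#' (equivalently `lambda f1 / (pi w0)`), hard-truncated at the aperture
#' radius.
#'
#' @param system An [optical_system()].
#' @param k Vacuum wavenumber (rad/um).
#' @return List with `w_pupil` (um), `Ra` (um), and `amplitude`, a function
#'   of pupil radius (um) that is zero beyond the aperture.
#' @export
pupil_field <- function(system, k) {
  w0 <- system$mfd / 2
  w_pupil <- 2 * system$f1 / (k * w0)
  if (w_pupil > 3 * system$Ra) {
    warning("pupil waist exceeds 3x the aperture radius: severe truncation")
  }
  Ra <- system$Ra
  list(w_pupil = w_pupil, Ra = Ra,
       amplitude = function(rho) exp(-(rho / w_pupil)^2) * (rho <= Ra))
}

# Richards-Wolf polarization strength vectors for x- and y-polarized input
rw_strength <- function(ct, st, cp, sp, pol) {
  ax <- cbind(ct * cp^2 + sp^2, (ct - 1) * sp * cp, -st * cp)
  ay <- cbind((ct - 1) * sp * cp, ct * sp^2 + cp^2, -st * sp)
  pol[1] * ax + pol[2] * ay
}

#' Vectorial focused field via the Debye-Wolf integral
#'
#' Angular-spectrum integration over the aperture cone with aplanatic
#' apodization `sqrt(cos theta)`: each pupil annulus maps to a plane wave
#' direction via the sine condition `rho = f2 sin theta`, carrying the
#' Richards-Wolf polarization rotation. The integral is evaluated by direct
#' quadrature (midpoint in theta, uniform in phi), accurate at the moderate
#' numerical apertures this model targets (NA < 0.5).
#'
#' @param system An [optical_system()].
#' @param k Vacuum wavenumber (rad/um).
#' @param x,y,z Coordinates (um) relative to the focus; vectors of equal
#'   length (or scalars, recycled). z along the optical axis.
#' @param medium_index Refractive index of the focal region (the in-medium
#'   wavenumber `k * medium_index` drives all propagation phases).
#' @param n_theta,n_phi Quadrature resolution.
#' @return Complex matrix (n x 3): Cartesian field components.
#' @export
debye_wolf_field <- function(system, k, x, y, z = 0, medium_index = 1,
                             n_theta = 48, n_phi = 64) {
  stopifnot(system$NA_obj < 0.5)
  npts <- max(length(x), length(y), length(z))
  x <- rep_len(x, npts); y <- rep_len(y, npts); z <- rep_len(z, npts)
  km <- k * medium_index
  theta_max <- asin(min(system$Ra / system$f2, 1))
  pup <- suppressWarnings(pupil_field(system, k))
  th <- (seq_len(n_theta) - 0.5) * theta_max / n_theta
  phv <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  dth <- theta_max / n_theta; dph <- 2 * pi / n_phi
  gr <- expand.grid(th = th, ph = phv)
  ct <- cos(gr$th); st <- sin(gr$th)
  cp <- cos(gr$ph); sp <- sin(gr$ph)
  amp <- pup$amplitude(system$f2 * st) * sqrt(ct) * st * dth * dph
  pvec <- rw_strength(ct, st, cp, sp, system$polarization)
  # phase: exp(i k_med (sx x + sy y + sz z)) evaluated in point chunks
  sx <- st * cp; sy <- st * sp; sz <- ct
  out <- matrix(0i, npts, 3)
  chunk <- max(1L, floor(2e6 / length(sx)))
  for (i0 in seq(1, npts, by = chunk)) {
    idx <- i0:min(npts, i0 + chunk - 1)
    ph <- exp(1i * km * (outer(x[idx], sx) + outer(y[idx], sy) +
                           outer(z[idx], sz)))
    for (c in 1:3) out[idx, c] <- ph %*% (amp * pvec[, c])
  }
  out
}

#' Focused illumination sampled on a PSTD source plane
#'
#' Evaluates the Debye-Wolf field at the carrier wavenumber on the cells of
#' a grid plane `S_ill` and packages it with the source timing parameters
#' (envelope width from the band, delay `t0 = 5 W`).
#'
#' @param system An [optical_system()].
#' @param k0 Carrier vacuum wavenumber (rad/um).
#' @param grid A [grid_spec()].
#' @param source_plane_z 1-based z index of S_ill (must lie inside the grid).
#' @param focus Numeric triple: focus position (um, grid coordinates; cell
#'   centers at (i - 1/2) * cell_size).
#' @param medium_index Index of the homogeneous region containing the plane.
#' @param W Envelope width (fs); default from [source_envelope_width()].
#' @param t0 Envelope delay (fs).
#' @return A [source_spec()].
#' @export
illumination_on_plane <- function(system, k0, grid, source_plane_z, focus,
                                  medium_index = grid$background_index,
                                  W = NULL, t0 = NULL) {
  d <- grid$dims
  if (source_plane_z < 1 || source_plane_z > d[3]) {
    stop("source plane lies outside the grid")
  }
  lam0 <- 2 * pi / k0
  if (grid$cell_size > lam0 / (4 * system$NA_obj)) {
    stop(sprintf(
      "aliasing: transverse sampling %.3g um exceeds lambda/(4 NA) = %.3g um",
      grid$cell_size, lam0 / (4 * system$NA_obj)))
  }
  if (is.null(W)) {
    W <- source_envelope_width(system$band_nm, system$lambda0_nm)
  }
  if (is.null(t0)) t0 <- 5 * W
  delta <- grid$cell_size
  xs <- ((seq_len(d[1]) - 0.5) * delta) - focus[1]
  ys <- ((seq_len(d[2]) - 0.5) * delta) - focus[2]
  zp <- (source_plane_z - 0.5) * delta - focus[3]
  gr <- expand.grid(x = xs, y = ys)
  e <- debye_wolf_field(system, k0, gr$x, gr$y, zp, medium_index)
  source_spec(z_index = source_plane_z,
              ex = matrix(e[, 1], d[1], d[2]),
              ey = matrix(e[, 2], d[1], d[2]),
              k0 = k0, W = W, t0 = t0)
}
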