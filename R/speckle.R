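#' Axial OCT amplitude point-spread function
#'
#' The complex axial response of the spectral-domain reconstruction: the
#' transform of the effective (Hanning) system spectrum with the round-trip
#' factor 2 and depths scaled from physical distance by the medium index
#' (`optical path = n z`).
#'
#' @param z Physical depth offsets (um).
#' @param band_nm Spectral band.
#' @param n_medium Medium refractive index.
#' @param n_k Spectral samples.
#' @return Complex vector (unnormalized).
#' @export
oct_axial_psf <- function(z, band_nm = c(1180, 1420), n_medium = 1.42,
                          n_k = 512) {
  k <- seq(2 * pi / (band_nm[2] / 1e3), 2 * pi / (band_nm[1] / 1e3),
           length.out = n_k)
  S <- hanning_spectrum(k, band_nm)
  as.vector(exp(1i * 2 * n_medium * outer(z, k)) %*% S)
}

#' Lateral OCT amplitude point-spread function (confocal)
#'
#' The image-domain lateral amplitude response of a fiber-coupled point
#' scanner is the product of the illumination profile and the coupling
#' (detection) profile; with a single fiber both equal the focused field, so
#' the lateral PSF is the square of the in-focus Debye-Wolf field.
#'
#' The transverse wavevector content is fixed by the air-side aperture and
#' preserved across the flat air-sample interface, so the lateral profile is
#' evaluated at the vacuum wavenumber (the medium index shifts focus axially
#' but does not shrink the lateral structure).
#'
#' @param x Lateral offsets (um).
#' @param system An [optical_system()].
#' @param k0 Carrier vacuum wavenumber (rad/um); default from the system.
#' @param medium_index Index used for the angular-spectrum phases; 1 by the
#'   interface argument above.
#' @return Complex vector (unnormalized).
#' @export
oct_lateral_psf <- function(x, system = optical_system(), k0 = NULL,
                            medium_index = 1) {
  if (is.null(k0)) k0 <- 2 * pi / (system$lambda0_nm / 1e3)
  e <- debye_wolf_field(system, k0, x, 0, 0, medium_index)
  e[, 1]^2
}

#' Simulate a fully developed speckle B-scan
#'
#' Convolves a dense field of random complex point scatterers (circular
#' Gaussian amplitudes, uniform positions, many per resolution cell) with
#' the separable system PSF: axial profile from [oct_axial_psf()], lateral
#' profile from [oct_lateral_psf()]. Returns the amplitude image.
#'
#' @param nz,nx Image size (axial x lateral samples).
#' @param dz,dx Sample spacings (um, physical).
#' @param system An [optical_system()].
#' @param n_medium Medium index (axial scaling).
#' @param density Scatterers per pixel (>= 20 per resolution cell once
#'   multiplied by the PSF area; the default is far above that).
#' @param seed RNG seed.
#' @return List: `image` (nz x nx amplitude matrix), `dz`, `dx`.
#' @export
simulate_speckle_bscan <- function(nz = 400, nx = 400, dz = 0.5, dx = 1.0,
                                   system = optical_system(),
                                   n_medium = 1.42, density = 2, seed = 1L) {
  z <- (seq_len(nz) - nz / 2 - 1) * dz
  x <- (seq_len(nx) - nx / 2 - 1) * dx
  hz <- oct_axial_psf(z, system$band_nm, n_medium)
  hx <- oct_lateral_psf(x, system)
  hz <- hz / max(Mod(hz)); hx <- hx / max(Mod(hx))
  H <- outer(hz, hx)
  # circular-Gaussian scatterer field: the continuous uniform-position limit
  # at >= `density` scatterers per pixel
  set.seed(seed)
  fld <- matrix(complex(real = stats::rnorm(nz * nx),
                        imaginary = stats::rnorm(nz * nx)), nz, nx) *
    sqrt(density)
  # cyclic convolution via FFT with the PSF re-centered on the origin
  Hs <- H[c((nz / 2 + 1):nz, 1:(nz / 2)), c((nx / 2 + 1):nx, 1:(nx / 2))]
  img <- stats::fft(stats::fft(fld) * stats::fft(Hs), inverse = TRUE) /
    (nz * nx)
  list(image = Mod(img), dz = dz, dx = dx)
}

#' Speckle autocovariance widths over seeds
#'
#' Runs [simulate_speckle_bscan()] for several seeds and reports the mean
#' axial and lateral FWHM of the normalized amplitude autocovariance.
#'
#' @param n_seeds Number of independent speckle realizations.
#' @param seed Base seed.
#' @param ... Passed to [simulate_speckle_bscan()].
#' @return List: `axial_fwhm_um`, `lateral_fwhm_um`, per-seed values.
#' @export
speckle_autocovariance_study <- function(n_seeds = 10, seed = 1L, ...) {
  ax <- numeric(n_seeds); lat <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    sim <- simulate_speckle_bscan(seed = seed + s - 1, ...)
    ax[s] <- normalized_autocovariance(sim$image, 1, sim$dz)$fwhm
    lat[s] <- normalized_autocovariance(sim$image, 2, sim$dx)$fwhm
  }
  list(axial_fwhm_um = mean(ax), lateral_fwhm_um = mean(lat),
       axial_by_seed = ax, lateral_by_seed = lat)
}
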