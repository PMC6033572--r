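#' Hanning system spectrum over a wavenumber band
#'
#' The effective system spectrum S(k) is modeled as a Hanning window
#' spanning the band (the measured spectrometer shape being out of scope).
#'
#' @param k Vacuum wavenumbers (rad/um).
#' @param band_nm Vacuum wavelength interval c(min, max), nm.
#' @return Non-negative weights, zero outside the band.
#' @export
hanning_spectrum <- function(k, band_nm = c(1180, 1420)) {
  kmin <- 2 * pi / (band_nm[2] / 1e3)
  kmax <- 2 * pi / (band_nm[1] / 1e3)
  u <- (k - kmin) / (kmax - kmin)
  ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

#' Scalar fiber-coupling overlap of two plane fields
#'
#' `alpha = integral (T e_ill)^T (T e_tot) d2r`: the transverse components
#' only, unconjugated product, trapezoidal quadrature on the plane grid.
#'
#' @param e_ill,e_tot Lists with complex matrices `ex`, `ey` sampled on the
#'   same detection plane.
#' @param cell_size Transverse sample spacing (um).
#' @return Complex scalar alpha.
#' @export
overlap_coupling <- function(e_ill, e_tot, cell_size) {
  if (!all(dim(e_ill$ex) == dim(e_tot$ex)) ||
      !all(dim(e_ill$ey) == dim(e_tot$ey))) {
    stop("illumination and total fields sampled on different grids")
  }
  d <- dim(e_ill$ex)
  wx <- if (d[1] > 1) c(0.5, rep(1, d[1] - 2), 0.5) else 1
  wy <- if (d[2] > 1) c(0.5, rep(1, d[2] - 2), 0.5) else 1
  w <- outer(wx, wy)
  sum(w * (e_ill$ex * e_tot$ex + e_ill$ey * e_tot$ey)) * cell_size^2
}

#' Coupling spectrum container
#'
#' @param wavenumbers Vacuum wavenumbers (rad/um), increasing.
#' @param alpha_tot Coupling with the sample in place.
#' @param alpha_ref Coupling with a mirror as the sample.
#' @param alpha_ill Coupling with a homogeneous grid.
#' @return An object of class `coupling_spectrum`.
#' @export
coupling_spectrum <- function(wavenumbers, alpha_tot, alpha_ref, alpha_ill) {
  n <- length(wavenumbers)
  stopifnot(length(alpha_tot) == n, length(alpha_ref) == n,
            length(alpha_ill) == n)
  structure(list(wavenumbers = wavenumbers, alpha_tot = alpha_tot,
                 alpha_ref = alpha_ref, alpha_ill = alpha_ill),
            class = "coupling_spectrum")
}

#' Interferometric detector power spectrum
#'
#' `i(k) = |alpha_tot - alpha_ill + alpha_ref - alpha_ill|^2` with the
#' proportionality constant fixed to 1 (absolute scale is absorbed into the
#' effective quantum efficiency). The illumination coupling is subtracted
#' from both terms because the source plane radiates in both axial
#' directions.
#'
#' @param coupling A [coupling_spectrum()].
#' @return Non-negative numeric vector i(k).
#' @export
interference_power <- function(coupling) {
  stopifnot(inherits(coupling, "coupling_spectrum"))
  Mod(coupling$alpha_tot - coupling$alpha_ill +
        coupling$alpha_ref - coupling$alpha_ill)^2
}

#' Detector model: effective quantum efficiency, window, seed
#'
#' @param eta Effective quantum efficiency (photons per unit optical power
#'   spectral sample); >= 0.
#' @param window `"hann"` or `"none"`: the effective spectrum S(k) applied
#'   during reconstruction.
#' @param band_nm Band for the window.
#' @param seed RNG seed for the shot-noise draws.
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(eta, window = c("hann", "none"),
                           band_nm = c(1180, 1420), seed = 1L) {
  stopifnot(eta >= 0)
  structure(list(eta = eta, window = match.arg(window), band_nm = band_nm,
                 seed = as.integer(seed)), class = "detector_model")
}

#' Apply Poisson shot noise to a detected spectrum
#'
#' The photon count in each spectral bin is `n(k) = eta i(k)`; shot noise
#' replaces it with a Poisson draw of that mean. Means above 1e7 use the
#' Gaussian limit of the Poisson distribution (relative skew < 3e-4 there).
#'
#' @param i_k Non-negative detected power spectrum.
#' @param detector A [detector_model()].
#' @return Noisy photon counts `n_tilde(k)`.
#' @export
apply_shot_noise <- function(i_k, detector) {
  if (any(i_k < 0)) stop("detected power must be non-negative")
  n_k <- detector$eta * i_k
  set.seed(detector$seed)
  out <- numeric(length(n_k))
  big <- n_k > 1e7
  out[!big] <- stats::rpois(sum(!big), n_k[!big])
  if (any(big)) {
    out[big] <- stats::rnorm(sum(big), n_k[big], sqrt(n_k[big]))
  }
  out
}

#' Reconstruct an A-scan from spectral measurements
#'
#' `A(z - z_ref) = (1 / 2 pi) sum S(k) n_tilde(k) exp(i 2 k (z - z_ref)) dk`
#' with the round-trip factor 2 in the exponent. `S(k)` is the effective
#' system spectrum (Hanning window by default). Displayed depth is optionally
#' scaled from optical to physical distance by the group index.
#'
#' @param n_tilde Spectral measurements (photon counts or any spectrum).
#' @param wavenumbers Uniformly spaced vacuum wavenumbers (rad/um).
#' @param detector A [detector_model()] (supplies the window).
#' @param z Optical depths (um) relative to z_ref at which to evaluate;
#'   default: the natural conjugate grid of the sampling.
#' @param n_group Group index used to scale displayed depth to physical
#'   distance (`z_physical = z / n_group`).
#' @return An object of class `ascan`: list with `z` (physical depth, um),
#'   `z_optical`, complex `A`, and the window used.
#' @export
reconstruct_ascan <- function(n_tilde, wavenumbers, detector, z = NULL,
                              n_group = 1) {
  n_k <- length(wavenumbers)
  dk <- diff(wavenumbers)
  if (n_k < 2 || max(abs(dk - dk[1])) > 1e-9 * dk[1]) {
    stop("wavenumbers must be uniformly spaced (resample first)")
  }
  dk <- dk[1]
  S <- switch(detector$window,
              hann = hanning_spectrum(wavenumbers, detector$band_nm),
              none = rep(1, n_k))
  if (is.null(z)) {
    zmax <- pi / (2 * dk)
    z <- seq(-zmax, zmax, length.out = n_k + 1)[seq_len(n_k)]
  }
  w <- S * n_tilde * dk / (2 * pi)
  A <- complex(length.out = length(z))
  chunk <- max(1L, floor(4e6 / n_k))
  for (i0 in seq(1, length(z), by = chunk)) {
    idx <- i0:min(length(z), i0 + chunk - 1)
    A[idx] <- exp(1i * 2 * outer(z[idx], wavenumbers)) %*% w
  }
  structure(list(z = z / n_group, z_optical = z, A = A,
                 window = detector$window, n_group = n_group),
            class = "ascan")
}

#' Mean region-of-interest SNR of reconstructed A-scans, in dB
#'
#' Ratio of mean signal power in a depth window to mean background power in
#' a signal-free depth window, `10 log10`.
#'
#' @param ascans List of `ascan` objects (or a single one).
#' @param signal_range,noise_range Depth intervals c(min, max) on the
#'   physical z axis.
#' @return SNR in dB.
#' @export
roi_snr_db <- function(ascans, signal_range, noise_range) {
  if (inherits(ascans, "ascan")) ascans <- list(ascans)
  pow <- function(a, rng) {
    sel <- a$z >= rng[1] & a$z <= rng[2]
    mean(Mod(a$A[sel])^2)
  }
  s <- mean(vapply(ascans, pow, numeric(1), rng = signal_range))
  n <- mean(vapply(ascans, pow, numeric(1), rng = noise_range))
  10 * log10(s / n)
}

#' Calibrate the effective quantum efficiency against a target SNR
#'
#' Bisection on log10(eta) until the mean ROI SNR of the reconstructed
#' (shot-noise corrupted) image is within `tol_db` of the target. The
#' shot-noise-limited SNR is monotone non-decreasing in eta.
#'
#' @param i_k_list List of detected power spectra i(k) (one per A-scan).
#' @param wavenumbers Uniform vacuum wavenumbers.
#' @param target_snr_db Target ROI SNR (dB).
#' @param signal_range,noise_range Depth windows for [roi_snr_db()].
#' @param detector Template [detector_model()] (window, band, seed).
#' @param n_group Group index for depth scaling.
#' @param log_eta_range Search bracket for log10(eta).
#' @param tol_db Convergence tolerance (dB).
#' @return The calibrated detector model (with `eta` set).
#' @export
calibrate_eta <- function(i_k_list, wavenumbers, target_snr_db,
                          signal_range, noise_range,
                          detector = detector_model(1),
                          n_group = 1, log_eta_range = c(-6, 12),
                          tol_db = 0.25) {
  snr_at <- function(log_eta) {
    det <- detector
    det$eta <- 10^log_eta
    asc <- lapply(seq_along(i_k_list), function(j) {
      det$seed <- detector$seed + j
      nt <- apply_shot_noise(i_k_list[[j]], det)
      reconstruct_ascan(nt, wavenumbers, det, n_group = n_group)
    })
    roi_snr_db(asc, signal_range, noise_range)
  }
  lo <- log_eta_range[1]; hi <- log_eta_range[2]
  # an eta so small that no photons are detected has no defined SNR;
  # treat it as below any target
  safe <- function(x) if (is.finite(x)) x else -Inf
  f_lo <- safe(snr_at(lo)) - target_snr_db
  f_hi <- safe(snr_at(hi)) - target_snr_db
  if (f_lo > 0 || f_hi < 0) {
    stop("calibration failure: target SNR not bracketed by the eta range")
  }
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    f_mid <- safe(snr_at(mid)) - target_snr_db
    if (abs(f_mid) <= tol_db) {
      detector$eta <- 10^mid
      return(detector)
    }
    if (f_mid > 0) hi <- mid else lo <- mid
  }
  stop("calibration failure: bisection did not converge")
}
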