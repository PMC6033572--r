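#' Normalized autocovariance of an image region with FWHM
#'
#' Mean-subtracts the region, computes the autocovariance along the chosen
#' axis by FFT (biased estimator), averages over the orthogonal axis, and
#' normalizes to 1 at zero lag. The FWHM of the (two-sided) central lobe is
#' found by linear interpolation of the half crossing.
#'
#' Computed on linear-amplitude images by convention (pass a dB image
#' explicitly if the logarithmic statistic is wanted).
#'
#' @param region Numeric matrix (amplitude image region).
#' @param axis 1 = along rows, 2 = along columns.
#' @param spacing Sample spacing along the chosen axis (um).
#' @return List: `lag` (um), `acov` (normalized), `fwhm` (um).
#' @export
normalized_autocovariance <- function(region, axis = 1, spacing = 1) {
  stopifnot(is.matrix(region), axis %in% 1:2)
  if (dim(region)[axis] < 32) stop("need at least 32 samples along the axis")
  a <- region - mean(region)
  if (stats::var(as.vector(a)) == 0) {
    stop("constant region: autocovariance undefined (zero variance)")
  }
  if (axis == 2) a <- t(a)
  n <- nrow(a)
  F <- stats::mvfft(a)
  ac <- Re(stats::mvfft(Mod(F)^2 + 0i, inverse = TRUE)) / n
  prof <- rowMeans(ac)
  prof <- prof / prof[1]
  half <- which(prof < 0.5)
  if (length(half) == 0) stop("autocovariance never falls below half maximum")
  i <- min(half)
  lag_half <- (i - 2 + (prof[i - 1] - 0.5) / (prof[i - 1] - prof[i])) * spacing
  list(lag = (seq_len(n) - 1) * spacing, acov = prof, fwhm = 2 * lag_half)
}

# connected components (26-connectivity) among a sparse set of voxels
label_components <- function(idx, dims) {
  if (nrow(idx) == 0) return(integer(0))
  key <- (idx[, 1] - 1) + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
  lookup <- new.env(hash = TRUE)
  for (r in seq_len(nrow(idx))) lookup[[as.character(key[r])]] <- r
  labels <- integer(nrow(idx))
  cur <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_len(nrow(idx))) {
    if (labels[r] > 0) next
    cur <- cur + 1L
    queue <- r
    labels[r] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- sweep(offs, 2, idx[v, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      nk <- (nb[, 1] - 1) + dims[1] * ((nb[, 2] - 1) + dims[2] * (nb[, 3] - 1))
      for (q in nk) {
        j <- lookup[[as.character(q)]]
        if (!is.null(j) && labels[j] == 0) {
          labels[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

# 1D Gaussian fit through a profile; returns center, fwhm, normalized rms
fit_gaussian_1d <- function(u, y) {
  peak <- max(y)
  u0 <- u[which.max(y)]
  s0 <- max(diff(u)[1], sqrt(sum(y * (u - u0)^2) / sum(y)))
  fit <- try(minpack.lm::nlsLM(
    y ~ a * exp(-(u - mu)^2 / (2 * s^2)) + b,
    start = list(a = peak, mu = u0, s = s0, b = min(y)),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(ok = FALSE, reason = "fit did not converge"))
  }
  cf <- stats::coef(fit)
  res <- sqrt(mean(stats::residuals(fit)^2)) / peak
  list(ok = TRUE, center = unname(cf["mu"]), sigma = abs(unname(cf["s"])),
       fwhm = 2 * sqrt(2 * log(2)) * abs(unname(cf["s"])), residual = res)
}

#' Extract isolated point-spread functions from a C-scan
#'
#' Thresholds the 3D amplitude image at the 99.95th percentile, labels
#' connected voxel volumes (26-connectivity), takes each component's maximum
#' as a candidate PSF center, and fits 1D Gaussians along x and z through
#' that center. Components whose normalized RMS fit residual exceeds
#' `residual_max` (typically merged multi-scatterer blobs) are rejected.
#'
#' @param cscan 3D amplitude array (x, y, z).
#' @param spacing Numeric triple: sample spacing per axis (um).
#' @param threshold_quantile Upper-tail quantile defining candidate voxels.
#' @param residual_max Rejection threshold on the normalized RMS residual.
#' @param halfwin Fit window half-width in samples.
#' @return data.frame with one row per accepted PSF: sub-pixel center
#'   (um), lateral and axial FWHM (um), fit residuals; rejected components
#'   are returned in attribute `"rejected"` with reasons.
#' @export
extract_psfs <- function(cscan, spacing = c(1, 1, 1),
                         threshold_quantile = 0.9995, residual_max = 0.15,
                         halfwin = 12) {
  d <- dim(cscan)
  # order-statistic threshold: exactly ceiling((1 - q) N) voxels selected
  # when values are untied
  n_sel <- ceiling((1 - threshold_quantile) * length(cscan))
  thr <- sort(cscan, decreasing = TRUE)[n_sel + 1]
  sel <- which(cscan > thr)
  if (length(sel) == 0) {
    return(structure(data.frame(), rejected = data.frame()))
  }
  idx <- arrayInd(sel, d)
  labels <- label_components(idx, d)
  rec <- list(); rej <- list()
  for (lab in seq_len(max(labels))) {
    vox <- idx[labels == lab, , drop = FALSE]
    vals <- cscan[vox]
    ctr <- vox[which.max(vals), ]
    win <- function(axis) {
      lo <- max(1, ctr[axis] - halfwin); hi <- min(d[axis], ctr[axis] + halfwin)
      lo:hi
    }
    ux <- win(1); uz <- win(3)
    fx <- fit_gaussian_1d(ux * spacing[1], cscan[ux, ctr[2], ctr[3]])
    fz <- fit_gaussian_1d(uz * spacing[3], cscan[ctr[1], ctr[2], uz])
    if (!fx$ok || !fz$ok) {
      rej[[length(rej) + 1]] <- data.frame(label = lab,
                                           reason = "fit did not converge")
      next
    }
    if (fx$residual > residual_max || fz$residual > residual_max) {
      rej[[length(rej) + 1]] <- data.frame(label = lab,
                                           reason = "residual above threshold")
      next
    }
    rec[[length(rec) + 1]] <- data.frame(
      x_um = fx$center, y_um = ctr[2] * spacing[2], z_um = fz$center,
      lateral_fwhm_um = fx$fwhm, axial_fwhm_um = fz$fwhm,
      residual_x = fx$residual, residual_z = fz$residual)
  }
  out <- if (length(rec)) do.call(rbind, rec) else data.frame()
  attr(out, "rejected") <- if (length(rej)) do.call(rbind, rej)
                           else data.frame()
  out
}

#' Resample PSF profiles onto a common axis
#'
#' Monotone piecewise-cubic Hermite interpolation (handles the sub-pixel
#' misalignment of individual PSFs before averaging).
#'
#' @param u Sample positions.
#' @param y Values.
#' @param u_out Common output positions.
#' @return Interpolated values.
#' @export
resample_profile <- function(u, y, u_out) {
  f <- stats::splinefun(u, y, method = "monoH.FC")
  f(u_out)
}

#' Lateral PSF width versus depth
#'
#' Bins accepted PSF records into axial windows of the given total depth and
#' reports the mean lateral FWHM and a two-standard-deviation spread per
#' bin; the minimum of the mean curve estimates the focus depth.
#'
#' @param psfs data.frame from [extract_psfs()].
#' @param bin_depth_um Total bin depth (um).
#' @return List: `profile` (data.frame z_center, mean_fwhm, spread2sd, n),
#'   `focus_z_um`.
#' @export
fwhm_vs_depth <- function(psfs, bin_depth_um = 40) {
  stopifnot(nrow(psfs) > 0)
  zr <- range(psfs$z_um)
  breaks <- seq(zr[1] - 1e-9, zr[2] + bin_depth_um, by = bin_depth_um)
  bin <- cut(psfs$z_um, breaks, labels = FALSE)
  rows <- lapply(sort(unique(bin)), function(b) {
    v <- psfs$lateral_fwhm_um[bin == b]
    data.frame(z_center = mean(breaks[b + 0:1]), mean_fwhm = mean(v),
               spread2sd = if (length(v) > 1) 2 * stats::sd(v) else 0,
               n = length(v))
  })
  prof <- do.call(rbind, rows)
  list(profile = prof, focus_z_um = prof$z_center[which.min(prof$mean_fwhm)])
}

#' Confocal-calibrated exponential attenuation fit
#'
#' Divides the high-scattering averaged intensity A-scan by the
#' low-scattering (calibration) average to remove the confocal envelope,
#' then fits `I = I0 exp(-2 mu_s (z - z0))` by nonlinear least squares.
#' `z0` is fixed at the start of the fit range (it is exchangeable with I0).
#' Uncertainty: many refits with Gaussian perturbations of each ratio point
#' (SD from `point_sd`, by default the residual SD of the first fit);
#' `mu_s_sigma` is the SD of the refit distribution.
#'
#' @param avg_high Averaged intensity A-scan of the scattering sample.
#' @param avg_calib Averaged intensity A-scan of the calibration sample
#'   (strictly positive over the fit range).
#' @param z Depth samples (um), physical distance.
#' @param fit_range Depth interval c(min, max) used for the fit.
#' @param point_sd Per-point SD of the ratio (scalar or vector); NULL to
#'   estimate from the fit residuals.
#' @param n_refits Number of perturbation refits.
#' @param seed RNG seed for the perturbations.
#' @return List of class `attenuation_fit`: `mu_s_mm`, `mu_s_sigma_mm`,
#'   `I0`, `z0_um`, `ratio`, `z_fit`.
#' @export
fit_attenuation <- function(avg_high, avg_calib, z, fit_range,
                            point_sd = NULL, n_refits = 500, seed = 1L) {
  sel <- z >= fit_range[1] & z <= fit_range[2]
  if (any(avg_calib[sel] <= 0)) {
    stop("calibration A-scan must be strictly positive over the fit range")
  }
  zf <- z[sel]
  ratio <- avg_high[sel] / avg_calib[sel]
  z0 <- fit_range[1]
  one_fit <- function(y) {
    ok <- y > 0
    lmfit <- stats::lm(log(y[ok]) ~ I(zf[ok] - z0))
    start <- list(I0 = exp(unname(stats::coef(lmfit)[1])),
                  mu = max(1e-6, -unname(stats::coef(lmfit)[2]) / 2 * 1e3))
    fit <- minpack.lm::nlsLM(y ~ I0 * exp(-2 * (mu / 1e3) * (zf - z0)),
                             start = start,
                             lower = c(I0 = 0, mu = 0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(fit)
  }
  cf <- one_fit(ratio)
  model <- cf["I0"] * exp(-2 * (cf["mu"] / 1e3) * (zf - z0))
  if (is.null(point_sd)) point_sd <- stats::sd(ratio - model)
  sdv <- rep_len(point_sd, length(ratio))
  set.seed(seed)
  mus <- vapply(seq_len(n_refits), function(i) {
    y <- ratio + stats::rnorm(length(ratio), 0, sdv)
    out <- try(one_fit(y), silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out["mu"]
  }, numeric(1))
  structure(list(mu_s_mm = unname(cf["mu"]),
                 mu_s_sigma_mm = stats::sd(mus, na.rm = TRUE),
                 I0 = unname(cf["I0"]), z0_um = z0,
                 ratio = ratio, z_fit = zf),
            class = "attenuation_fit")
}

#' Amplitude histogram with Rayleigh fit
#'
#' Histograms linear amplitudes, fits the Rayleigh scale by maximum
#' likelihood (`sigma^2 = mean(a^2) / 2`), and reports the one-sample
#' Kolmogorov-Smirnov statistic and p-value against the fitted Rayleigh
#' distribution.
#'
#' @param amplitudes Linear (non-negative) amplitude samples, >= 200.
#' @param n_bins Histogram bin count.
#' @return List: `mids`, `density`, `sigma` (Rayleigh scale), `ks_stat`,
#'   `ks_p`.
#' @export
amplitude_histogram <- function(amplitudes, n_bins = 50) {
  stopifnot(length(amplitudes) >= 200)
  if (stats::var(amplitudes) == 0) {
    warning("degenerate input: all amplitudes equal")
    return(list(mids = mean(amplitudes), density = Inf,
                sigma = NA_real_, ks_stat = NA_real_, ks_p = NA_real_))
  }
  h <- graphics::hist(amplitudes, breaks = n_bins, plot = FALSE)
  sigma <- sqrt(mean(amplitudes^2) / 2)
  ks <- suppressWarnings(stats::ks.test(
    amplitudes, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  list(mids = h$mids, density = h$density, sigma = sigma,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}
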