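# Speed of light in internal units (um / fs)
C_UM_FS <- 0.299792458

#' Next FFT-friendly size
#'
#' Smallest integer >= n whose prime factors are all in {2, 3, 5}; the FFT
#' work per solver step depends strongly on the factorization of the grid
#' dimensions.
#'
#' @param n Lower bound.
#' @return A 5-smooth integer >= n.
#' @export
fft_good_size <- function(n) {
  m <- as.integer(n)
  repeat {
    r <- m
    for (p in c(2L, 3L, 5L)) while (r %% p == 0L) r <- r %/% p
    if (r == 1L) return(m)
    m <- m + 1L
  }
}

#' Uniform cubic grid specification
#'
#' Defines the PSTD computational grid: isotropic cell size, dimensions
#' (1D/2D degenerate grids are supported through singleton axes), the
#' matched absorbing boundary layer, and the background refractive index.
#' Cell centers sit at `((i - 1/2) * cell_size)` from the grid corner along
#' each axis; the z axis is the optical axis.
#'
#' @param cell_size Cell edge length (micrometres).
#' @param dims Integer triple, cells per axis.
#' @param pml_thickness Absorber thickness in cells per boundary face
#'   (applied to every non-singleton axis; 0 disables absorption and the
#'   FFT derivatives make the axis periodic).
#' @param pml_order Polynomial grading order of the absorber conductivity.
#' @param pml_target_amplitude Design one-pass round-trip amplitude
#'   attenuation of the absorber (sets the peak conductivity).
#' @param background_index Background refractive index filling the grid.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(cell_size, dims, pml_thickness = 10, pml_order = 3,
                      pml_target_amplitude = 1e-4, background_index = 1) {
  dims <- as.integer(dims)
  stopifnot(cell_size > 0, length(dims) == 3, all(dims >= 1),
            pml_thickness >= 0, background_index >= 1)
  interior <- dims - ifelse(dims > 1, 2L * pml_thickness, 0L)
  if (any(interior < 1)) stop("no interior cells left after removing the absorber")
  structure(list(cell_size = cell_size, dims = dims,
                 pml_thickness = as.integer(pml_thickness),
                 pml_order = pml_order,
                 pml_target_amplitude = pml_target_amplitude,
                 background_index = background_index),
            class = "grid_spec")
}

#' Check Nyquist sampling of a grid against a wavelength band
#'
#' The PSTD grid must sample the shortest in-medium wavelength at or above
#' the Nyquist rate: `cell_size <= lambda_min / (2 n_max)`.
#'
#' @param grid A [grid_spec()].
#' @param lambda_min Shortest vacuum wavelength to be propagated (um).
#' @param n_max Largest refractive index present.
#' @return `TRUE` invisibly; stops if the grid is undersampled.
#' @export
check_nyquist <- function(grid, lambda_min, n_max) {
  if (grid$cell_size > lambda_min / (2 * n_max)) {
    stop(sprintf("grid undersampled: cell_size %.4g > lambda_min/(2 n_max) = %.4g",
                 grid$cell_size, lambda_min / (2 * n_max)))
  }
  invisible(TRUE)
}

#' Leapfrog stability limit of the PSTD update
#'
#' The collocated FFT-derivative leapfrog scheme is stable for
#' `dt <= 2 * cell_size / (c_max * pi * sqrt(D))` where `D` is the number of
#' non-singleton grid dimensions and `c_max = c / n_min` the fastest phase
#' velocity on the grid.
#'
#' @param grid A [grid_spec()].
#' @param n_min Smallest refractive index on the grid.
#' @return Maximum stable time step (fs).
#' @export
stability_limit <- function(grid, n_min = 1) {
  D <- sum(grid$dims > 1)
  if (D == 0) stop("grid has no extended dimension")
  c_max <- C_UM_FS / n_min
  2 * grid$cell_size / (c_max * pi * sqrt(D))
}

# graded conductivity profile along one axis; returns per-cell damping rate
pml_gamma_axis <- function(n_cells, thickness, order, target_amplitude,
                           v_background, cell_size) {
  g <- numeric(n_cells)
  if (thickness == 0 || n_cells == 1) return(g)
  L <- thickness * cell_size
  gamma_max <- -log(target_amplitude) * (order + 1) * v_background / (2 * L)
  i <- seq_len(n_cells) - 1
  lo <- pmax(0, (thickness - i - 0.5) / thickness)
  hi <- pmax(0, (i + 0.5 - (n_cells - thickness)) / thickness)
  gamma_max * (pmax(lo, hi)^order)
}

#' Per-cell damping factors of the matched absorbing boundary
#'
#' Builds the multiplicative per-step damping cube `exp(-gamma(r) dt)` with
#' polynomially graded conductivity on each non-singleton axis, applied
#' identically to E and H (impedance matched at normal incidence).
#'
#' @param grid A [grid_spec()].
#' @param dt Time step (fs).
#' @return A 3D array of damping factors in (0, 1].
#' @export
pml_damping <- function(grid, dt) {
  d <- grid$dims
  v <- C_UM_FS / grid$background_index
  gx <- if (d[1] > 1) pml_gamma_axis(d[1], grid$pml_thickness, grid$pml_order,
                                     grid$pml_target_amplitude, v, grid$cell_size) else 0
  gy <- if (d[2] > 1) pml_gamma_axis(d[2], grid$pml_thickness, grid$pml_order,
                                     grid$pml_target_amplitude, v, grid$cell_size) else 0
  gz <- if (d[3] > 1) pml_gamma_axis(d[3], grid$pml_thickness, grid$pml_order,
                                     grid$pml_target_amplitude, v, grid$cell_size) else 0
  g <- outer(outer(rep(gx, length.out = d[1]), rep(gy, length.out = d[2]), `+`),
             rep(gz, length.out = d[3]), `+`)
  array(exp(-g * dt), dim = d)
}

#' Spectral derivative of a uniformly sampled line
#'
#' d/dz by forward FFT, multiplication by i k, inverse FFT. The transform is
#' periodic; in solver runs the absorbing layer removes wrap-around energy.
#' The Nyquist bin is zeroed (odd derivative of the unresolved mode).
#'
#' @param line Real or complex values, uniformly sampled, length >= 4.
#' @param cell_size Sample spacing.
#' @return Derivative, same length and type as the input.
#' @export
spectral_derivative <- function(line, cell_size) {
  n <- length(line)
  if (n < 4) stop("need at least 4 uniformly sampled values")
  if (!is.numeric(line) && !is.complex(line)) stop("invalid input line")
  if (anyNA(line)) stop("invalid input line")
  dk <- 2 * pi / (n * cell_size)
  j <- 0:(n - 1)
  k <- dk * ifelse(j <= (n - 1) %/% 2, j, j - n)
  if (n %% 2 == 0) k[n / 2 + 1] <- 0
  out <- fft(fft(line) * (1i * k), inverse = TRUE) / n
  if (is.complex(line)) out else Re(out)
}

#' Source specification: planar magnetic current density
#'
#' Packages the time-modulated magnetic current sheet that injects the
#' focused illumination: `J*(t) = Re{-k_hat x e_ill exp(-i omega0 (t - t0))}
#' exp(-pi ((t - t0) / W)^2)` on the plane `z = z_index`.
#'
#' @param z_index 1-based z index of the source plane S_ill.
#' @param ex,ey Complex matrices (nx x ny): transverse illumination field at
#'   the carrier wavenumber on the source plane.
#' @param k0 Carrier vacuum wavenumber (rad/um).
#' @param W Gaussian envelope width (fs).
#' @param t0 Envelope delay (fs); must leave negligible amplitude at t = 0.
#' @param k_hat +1 for launch bookkeeping along +z, -1 to reverse.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(z_index, ex, ey, k0, W, t0 = 5 * W, k_hat = 1) {
  stopifnot(is.matrix(ex), is.matrix(ey), all(dim(ex) == dim(ey)),
            k0 > 0, W > 0, t0 > 0, k_hat %in% c(-1, 1))
  # omega0 = c k0 with vacuum c and vacuum k0 (the printed c/k0 is not an
  # angular frequency dimensionally; see the methods vignette)
  if (exp(-pi * (t0 / W)^2) > 1e-6) {
    stop("t0 too small: envelope magnitude at t = 0 exceeds 1e-6 of peak")
  }
  structure(list(z_index = as.integer(z_index), ex = ex, ey = ey, k0 = k0,
                 omega0 = C_UM_FS * k0, t0 = t0, W = W, k_hat = k_hat),
            class = "source_spec")
}

#' Envelope width covering a spectral band
#'
#' Chooses the Gaussian envelope width W so that the source amplitude
#' spectrum is at least `edge_level` of its peak at both band edges.
#'
#' @param band_nm Vacuum wavelength interval, c(min, max), nm.
#' @param lambda0_nm Central vacuum wavelength, nm.
#' @param edge_level Required relative amplitude at the band edges.
#' @return W in fs.
#' @export
source_envelope_width <- function(band_nm = c(1180, 1420), lambda0_nm = 1300,
                                  edge_level = 0.1) {
  om <- 2 * pi * C_UM_FS / (band_nm / 1e3)
  om0 <- 2 * pi * C_UM_FS / (lambda0_nm / 1e3)
  dom <- max(abs(om - om0))
  sqrt(-4 * pi * log(edge_level)) / dom
}

#' Evaluate the source magnetic current density at a time
#'
#' @param source A [source_spec()].
#' @param t Time (fs), >= 0.
#' @return List with real matrices `Jx`, `Jy` on the source plane.
#' @export
inject_source_waveform <- function(source, t) {
  stopifnot(inherits(source, "source_spec"), t >= 0)
  ph <- exp(-1i * source$omega0 * (t - source$t0)) *
    exp(-pi * ((t - source$t0) / source$W)^2)
  # J* = Re{-k_hat z_hat x e}: for k_hat = +1, Jx = Re(ey ph), Jy = -Re(ex ph)
  list(Jx = source$k_hat * Re(source$ey * ph),
       Jy = -source$k_hat * Re(source$ex * ph))
}

#' Analytic amplitude spectrum of the source envelope
#'
#' Fourier transform (with the repo-wide `exp(+i omega t)` convention) of
#' `exp(-i omega0 (t - t0)) exp(-pi ((t - t0)/W)^2)`.
#'
#' @param source A [source_spec()].
#' @param omegas Angular frequencies (rad/fs).
#' @return Complex vector G(omega).
#' @export
source_spectrum <- function(source, omegas) {
  dom <- omegas - source$omega0
  source$W * exp(1i * omegas * source$t0) * exp(-dom^2 * source$W^2 / (4 * pi))
}

#' Running spectral accumulator (R-level)
#'
#' Creates a spectral probe that accumulates running discrete Fourier
#' transforms of sampled field values: each call to [accumulate_spectrum()]
#' adds `value * exp(+i omega t) * dt` for every configured wavenumber. The
#' solver kernel performs the same accumulation internally; this R-level
#' tool serves step-by-step diagnostics with [step_fields()].
#'
#' @param wavenumbers Vacuum wavenumbers (rad/um), strictly increasing.
#' @param n_values Number of scalar values accumulated per call.
#' @return An object of class `spectral_probe`.
#' @export
spectral_probe <- function(wavenumbers, n_values = 1) {
  stopifnot(length(wavenumbers) >= 1,
            length(wavenumbers) == 1 || all(diff(wavenumbers) > 0))
  structure(list(wavenumbers = wavenumbers,
                 omegas = C_UM_FS * wavenumbers,
                 acc = matrix(0i, n_values, length(wavenumbers)),
                 n_acc = 0L, finalized = FALSE),
            class = "spectral_probe")
}

#' Accumulate one time sample into a spectral probe
#'
#' @param probe A [spectral_probe()].
#' @param values Field sample(s) at time `t`.
#' @param t Sample time (fs).
#' @param dt Time step (fs).
#' @return The updated probe.
#' @export
accumulate_spectrum <- function(probe, values, t, dt) {
  stopifnot(inherits(probe, "spectral_probe"),
            length(values) == nrow(probe$acc))
  probe$acc <- probe$acc + outer(values, exp(1i * probe$omegas * t)) * dt
  probe$n_acc <- probe$n_acc + 1L
  probe
}

#' Finalize a spectral probe against the source spectrum
#'
#' Divides the accumulated spectra by the analytic source envelope spectrum
#' so that amplitudes are normalized per unit source excitation. Warns if
#' fewer samples than the configured iteration count were accumulated.
#'
#' @param probe A [spectral_probe()].
#' @param source A [source_spec()].
#' @param expected_steps Configured iteration count (optional).
#' @return The probe with normalized `acc` and `finalized = TRUE`.
#' @export
finalize_probe <- function(probe, source, expected_steps = NULL) {
  if (!is.null(expected_steps) && probe$n_acc < expected_steps) {
    warning("incomplete accumulation: fewer samples than configured")
  }
  G <- source_spectrum(source, probe$omegas)
  probe$acc <- sweep(probe$acc, 2, G, `/`)
  probe$finalized <- TRUE
  probe
}

#' Run the PSTD solver
#'
#' Advances Maxwell's equations with FFT spatial derivatives and leapfrog
#' time stepping. Optionally injects a planar source, accumulates running
#' DFTs of the fields at probe points / on a detection plane / as
#' fiber-coupling overlaps, records time series, and tracks a discrete
#' energy diagnostic.
#'
#' @param grid A [grid_spec()].
#' @param n Refractive index array matching `grid$dims`; default homogeneous
#'   at the grid background index.
#' @param source Optional [source_spec()].
#' @param nsteps Number of leapfrog iterations.
#' @param dt Time step (fs); default 0.95 of [stability_limit()].
#' @param wavenumbers Vacuum wavenumbers (rad/um) for running DFTs.
#' @param probe_points Optional integer matrix (npts x 3, 1-based cell
#'   indices) where spectral E and H are accumulated.
#' @param plane_z Optional 1-based z index of a plane on which spectral
#'   transverse E is accumulated.
#' @param alpha_weights Optional list(wx, wy) of complex arrays
#'   (nx x ny x n_k): per-wavenumber illumination weights for incremental
#'   coupling on `plane_z`.
#' @param ts_points Optional integer matrix (n x 3): record Ex and Hy time
#'   series at these cells.
#' @param sf_source Optional scattered-field contrast source (list with
#'   0-based `idx`, `coef`, `z_rel`, `v`, `omega0`, `t0`, `W`): drives Ex
#'   with the analytic incident plane-wave pulse inside the listed cells.
#' @param init Optional initial fields (list Ex..Hz) for continuation runs.
#' @param pec Optional 0/1 array marking perfect-conductor cells.
#' @param energy_trace Record the conserved leapfrog energy each step.
#' @param return_fields Return final field arrays.
#' @param verbose Print a field-max line every 100 iterations.
#' @return List with accumulated spectra, coupling, diagnostics. Probe
#'   spectra are `npts x n_k x 3` complex arrays `probe_E`, `probe_H`.
#' @export
pstd_simulate <- function(grid, n = NULL, source = NULL, nsteps,
                          dt = NULL, wavenumbers = NULL, probe_points = NULL,
                          plane_z = NULL, alpha_weights = NULL,
                          ts_points = NULL, init = NULL, pec = NULL,
                          sf_source = NULL, energy_trace = FALSE,
                          return_fields = FALSE, verbose = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), nsteps >= 1)
  if (is.null(n)) n <- array(grid$background_index, dim = grid$dims)
  stopifnot(all(dim(n) == grid$dims), all(is.finite(n)), all(n >= 1))
  lim <- stability_limit(grid, n_min = min(n))
  if (is.null(dt)) dt <- 0.95 * lim
  if (dt > lim * (1 + 1e-12)) {
    stop(sprintf("dt = %.4g fs exceeds the stability limit %.4g fs", dt, lim))
  }
  cfg <- list(n = n, damp = pml_damping(grid, dt), cell_size = grid$cell_size,
              dt = dt, nsteps = as.integer(nsteps), c0 = C_UM_FS,
              diverge_threshold = 1e6 * 1e3)
  if (!is.null(source)) {
    src_dims <- grid$dims[1:2]
    stopifnot(all(dim(source$ex) == src_dims))
    cfg$source <- list(z_index = source$z_index - 1L,
                       ex = source$k_hat * source$ex,
                       ey = source$k_hat * source$ey,
                       omega0 = source$omega0, t0 = source$t0, W = source$W)
  }
  if (!is.null(wavenumbers)) {
    stopifnot(all(diff(wavenumbers) > 0) || length(wavenumbers) == 1)
    cfg$omegas <- C_UM_FS * wavenumbers
  }
  if (!is.null(probe_points)) {
    cfg$probe_idx <- as.matrix(probe_points) - 1L
    storage.mode(cfg$probe_idx) <- "integer"
  }
  cfg$plane_z <- if (is.null(plane_z)) -1L else as.integer(plane_z) - 1L
  if (!is.null(alpha_weights)) cfg$alpha_weights <- alpha_weights
  if (!is.null(ts_points)) {
    cfg$ts_idx <- as.matrix(ts_points) - 1L
    storage.mode(cfg$ts_idx) <- "integer"
  }
  if (!is.null(init)) cfg$init <- init
  if (!is.null(pec)) cfg$pec <- pec
  if (!is.null(sf_source)) cfg$sf_source <- sf_source
  cfg$energy_trace <- energy_trace
  cfg$return_fields <- return_fields
  out <- pstd_run_cpp(cfg)
  if (out$diverged) {
    stop(sprintf("PSTD simulation diverged after %d steps (dt = %.4g fs)",
                 out$steps_done, dt))
  }
  if (verbose) {
    fm <- out$fieldmax
    idx <- seq(1, length(fm), by = 5)
    for (i in idx) message(sprintf("iter %5d  max|E| = %.3e", (i - 1) * 20, fm[i]))
  }
  if (!is.null(out$probe_E)) {
    np <- nrow(out$probe_E[[1]]); nk <- ncol(out$probe_E[[1]])
    pe <- array(0i, c(np, nk, 3)); ph <- array(0i, c(np, nk, 3))
    for (c in 1:3) { pe[, , c] <- out$probe_E[[c]]; ph[, , c] <- out$probe_H[[c]] }
    out$probe_E <- pe; out$probe_H <- ph
  }
  out$dt <- dt
  out$wavenumbers <- wavenumbers
  out
}

#' Advance a field state by one leapfrog step
#'
#' Single-step interface around the solver kernel: H is advanced by dt
#' (including the source magnetic current), then E by dt. Useful for
#' step-by-step diagnostics and the R-level spectral accumulation tools.
#'
#' @param state List with arrays Ex, Ey, Ez, Hx, Hy, Hz, integer `t_index`,
#'   and `dt` (fs). Use [new_field_state()] to create a zero state.
#' @param grid A [grid_spec()].
#' @param n Refractive index array (default homogeneous).
#' @param source Optional [source_spec()].
#' @return The advanced state.
#' @export
step_fields <- function(state, grid, n = NULL, source = NULL) {
  out <- pstd_simulate(grid, n = n, source = source, nsteps = 1,
                       dt = state$dt,
                       init = state[c("Ex", "Ey", "Ez", "Hx", "Hy", "Hz")],
                       return_fields = TRUE)
  st <- out$fields
  st$t_index <- state$t_index + 1L
  st$dt <- state$dt
  st
}

#' Create an all-zero field state
#'
#' @param grid A [grid_spec()].
#' @param dt Time step (fs); default 0.95 of the vacuum [stability_limit()].
#' @return A field-state list for [step_fields()].
#' @export
new_field_state <- function(grid, dt = NULL) {
  if (is.null(dt)) dt <- 0.95 * stability_limit(grid)
  z <- array(0, dim = grid$dims)
  list(Ex = z, Ey = z, Ez = z, Hx = z, Hy = z, Hz = z,
       t_index = 0L, dt = dt)
}

#' Measure the absorbing-boundary reflection coefficient
#'
#' Launches a 1D pulse at normal incidence onto the grid's absorber and
#' returns the ratio of the maximum reflected amplitude to the incident
#' peak, measured at a probe between the source and the far boundary.
#'
#' @param grid A [grid_spec()] (its z extent and absorber settings are used;
#'   measurement runs on a 1D reduction).
#' @param lambda0 Carrier vacuum wavelength (um).
#' @return Amplitude reflection coefficient (power reflection is its square).
#' @export
measure_pml_reflection <- function(grid, lambda0 = 1.3) {
  nzc <- max(grid$dims[3], 240L)
  g1 <- grid_spec(grid$cell_size, c(1, 1, nzc),
                  pml_thickness = grid$pml_thickness,
                  pml_order = grid$pml_order,
                  pml_target_amplitude = grid$pml_target_amplitude,
                  background_index = grid$background_index)
  k0 <- 2 * pi / lambda0
  W <- 6
  src <- source_spec(z_index = max(grid$pml_thickness + 2L, 3L),
                     ex = matrix(1 + 0i, 1, 1), ey = matrix(0i, 1, 1),
                     k0 = k0, W = W, t0 = 2.2 * W)
  probe_z <- as.integer(round(nzc * 0.55))
  dt <- 0.95 * stability_limit(g1, n_min = grid$background_index)
  v <- C_UM_FS / grid$background_index
  # time for the pulse to reach the probe, hit the far absorber, and return
  t_probe <- src$t0 + (probe_z - src$z_index) * g1$cell_size / v
  t_return <- t_probe + 2.2 * nzc * g1$cell_size / v  # covers wrap-around too
  nsteps <- ceiling((t_return + 8 * W) / dt)
  out <- pstd_simulate(g1, source = src, nsteps = nsteps, dt = dt,
                       ts_points = matrix(c(1L, 1L, probe_z), 1))
  ts <- out$tsEx[, 1]
  tt <- (seq_along(ts)) * dt
  inc_window <- tt < (t_probe + 4 * W)
  inc_peak <- max(abs(ts[inc_window]))
  refl_window <- tt > (t_probe + 5 * W)
  if (!any(refl_window)) stop("run too short to observe reflection")
  refl_peak <- max(abs(ts[refl_window]))
  refl_peak / inc_peak
}
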