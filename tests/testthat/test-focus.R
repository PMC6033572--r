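sys_default <- optical_system()

test_that("fiber mode has the defining MFD geometry and unit energy", {
  f <- fiber_mode(9.2)
  expect_equal(f(9.2 / 2)^2 / f(0)^2, exp(-2))
  # for exp(-r^2/w0^2) the amplitude 1/e radius coincides with the 1/e^2
  # intensity radius mfd/2
  expect_equal(f(9.2 / 2) / f(0), exp(-1), tolerance = 1e-12)
  energy <- stats::integrate(function(r) 2 * pi * r * f(r)^2, 0, Inf,
                             rel.tol = 1e-10)$value
  expect_lt(abs(energy - 1), 1e-8)
})

test_that("pupil field is the Fourier image of the fiber mode", {
  p <- pupil_field(sys_default, k0)
  # Gaussian-beam transform identity: w_pupil = lambda f1 / (pi w0)
  expect_equal(p$w_pupil, 1.3 * 25000 / (pi * 4.6), tolerance = 1e-12)
  expect_lt(p$w_pupil, sys_default$Ra)          # mild truncation
  expect_equal(p$amplitude(3501), 0)            # zero outside the aperture
  expect_gt(p$amplitude(3499), 0)
  expect_warning(pupil_field(optical_system(mfd_um = 1.2), k0), "truncation")
})

test_that("system NA and focal polarization behave as vectorial theory", {
  expect_equal(sys_default$NA_obj, 3.5 / 36, tolerance = 1e-12)
  x <- seq(-15, 15, by = 1)
  e_ax <- debye_wolf_field(sys_default, k0, x, 0, 0)
  e_di <- debye_wolf_field(sys_default, k0, x, x, 0)
  ex_peak <- max(Mod(e_ax[, 1]))
  expect_lt(max(Mod(e_di[, 2])) / ex_peak, 1e-3)   # cross-polarization
  expect_lt(max(Mod(e_ax[, 3])) / ex_peak, 0.05)   # longitudinal component
})

test_that("low-NA focus matches the paraxial Gaussian closed form", {
  sys_open <- optical_system(Ra_mm = 12)   # untruncated Gaussian pupil
  p <- suppressWarnings(pupil_field(sys_open, k0))
  x <- seq(-25, 25, by = 0.1)
  prof <- Mod(debye_wolf_field(sys_open, k0, x, 0, 0, n_theta = 96)[, 1])
  w_f <- 1.3 * 36000 / (pi * p$w_pupil)
  expect_lt(abs(profile_fwhm(x, prof) / (2 * sqrt(log(2)) * w_f) - 1), 0.03)
})

test_that("focal energy is conserved across planes", {
  gx <- seq(-60, 60, by = 1.5)
  gg <- expand.grid(x = gx, y = gx)
  en <- vapply(c(0, 100, 200), function(zz) {
    e <- debye_wolf_field(sys_default, k0, gg$x, gg$y, zz)
    sum(Mod(e)^2)
  }, numeric(1))
  expect_lt(max(abs(en / en[1] - 1)), 0.01)
})

test_that("focal width scales linearly with wavelength for a fixed aperture", {
  # aperture-filling mode: the pupil is set by Ra, so FWHM ~ lambda
  sys_fill <- suppressWarnings(optical_system(mfd_um = 1.5))
  x <- seq(-20, 20, by = 0.05)
  f <- vapply(c(1.18, 1.42), function(lam) {
    profile_fwhm(x, Mod(suppressWarnings(
      debye_wolf_field(sys_fill, 2 * pi / lam, x, 0, 0))[, 1]))
  }, numeric(1))
  expect_equal(f[2] / f[1], 1.42 / 1.18, tolerance = 0.02)
})

test_that("illumination sampled on a grid plane translates with the focus", {
  g <- grid_spec(lam0 / 6, c(36, 36, 40), pml_thickness = 8)
  ctr <- c(18, 18, 30) * g$cell_size
  s1 <- illumination_on_plane(sys_default, k0, g, 12, ctr, W = 8)
  s2 <- illumination_on_plane(sys_default, k0, g, 12,
                              ctr + c(2 * g$cell_size, 0, 0), W = 8)
  # a lateral focus shift by 2 cells shifts the plane field by 2 cells
  expect_lt(max(Mod(s2$ex[3:36, ] - s1$ex[1:34, ])),
            1e-6 * max(Mod(s1$ex)))
  # undersampled transverse grid is refused (aliasing guard)
  g_coarse <- grid_spec(4.0, c(12, 12, 16), pml_thickness = 0)
  sys_na <- suppressWarnings(optical_system(mfd_um = 1.5))   # aperture-filling
  expect_error(illumination_on_plane(sys_na, k0, g_coarse, 4,
                                     c(24, 24, 30), W = 8),
               "aliasing")
  # plane through the focus reproduces the in-focus profile
  s0 <- illumination_on_plane(sys_default, k0, g, 12,
                              c(ctr[1], ctr[2], 11.5 * g$cell_size), W = 8)
  xs <- (seq_len(36) - 0.5) * g$cell_size - ctr[1]
  ref <- debye_wolf_field(sys_default, k0, xs, rep(-ctr[2], 36) +
                            17.5 * g$cell_size, 0, g$background_index)
  expect_lt(max(Mod(Mod(s0$ex[, 18]) / max(Mod(s0$ex)) -
                      Mod(ref[, 1]) / max(Mod(ref[, 1])))), 0.02)
})

test_that("PSTD propagation of the injected source reproduces the focus", {
  # cross-module consistency: launch the Debye-Wolf field from S_ill on a
  # homogeneous grid and compare the propagated spectral field on the focal
  # plane with the directly evaluated Debye-Wolf field (higher NA so the
  # focal structure fits the desk-scale grid)
  sys_hi <- suppressWarnings(optical_system(Ra_mm = 12, mfd_um = 2.5))
  g <- grid_spec(lam0 / 6, c(48, 48, 60), pml_thickness = 10,
                 background_index = 1)
  delta <- g$cell_size
  focus <- c(24, 24, 38) * delta
  src <- illumination_on_plane(sys_hi, k0, g, source_plane_z = 14,
                               focus = focus, W = 8, t0 = 20)
  dt <- 0.45 * stability_limit(g)
  out <- pstd_simulate(g, source = src, nsteps = 1500, dt = dt,
                       wavenumbers = k0, plane_z = 38)
  sim <- out$plane_Ex[, , 1]
  xs <- (seq_len(48) - 0.5) * delta - focus[1]
  ys <- (seq_len(48) - 0.5) * delta - focus[2]
  gr <- expand.grid(x = xs, y = ys)
  ref <- matrix(debye_wolf_field(sys_hi, k0, gr$x, gr$y,
                                 (38 - 0.5) * delta - focus[3])[, 1], 48, 48)
  # compare within the central region, away from absorber-edge taper
  w <- 13:36
  a <- Mod(sim[w, w]); b <- Mod(ref[w, w])
  a <- a / max(a); b <- b / max(b)
  expect_lt(sqrt(mean((a - b)^2)) / max(b), 0.05)
})
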