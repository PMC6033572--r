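test_that("spectral derivative is exact on resolved modes", {
  n <- 64; delta <- 0.25
  L <- n * delta
  expect_equal(spectral_derivative(rep(3.7, n), delta), rep(0, n))
  z <- (0:(n - 1)) * delta
  for (m in c(1, 5)) {
    d <- spectral_derivative(sin(2 * pi * m * z / L), delta)
    expect_lt(max(abs(d - (2 * pi * m / L) * cos(2 * pi * m * z / L))), 1e-12)
  }
  expect_error(spectral_derivative(c(1, 2, 3), delta), "at least 4")
  expect_error(spectral_derivative(c(1, NA, 3, 4), delta), "invalid")
})

test_that("spectral derivative matches high-order finite differences", {
  # oracle: 8th-order central differences on an 8x oversampled copy of a
  # band-limited random signal
  set.seed(42)
  n <- 64; over <- 8; delta <- 0.3
  nf <- n * over
  spec <- rep(0i, nf)
  keep <- 2:(n / 4)   # band-limited well below the coarse Nyquist
  spec[keep] <- complex(real = rnorm(length(keep)),
                        imaginary = rnorm(length(keep)))
  spec[nf - keep + 2] <- Conj(spec[keep])
  fine <- Re(fft(spec, inverse = TRUE)) / nf
  h <- delta / over
  w <- c(1 / 280, -4 / 105, 1 / 5, -4 / 5, 0, 4 / 5, -1 / 5, 4 / 105, -1 / 280)
  idx <- function(s) fine[((0:(nf - 1)) + s) %% nf + 1]
  d_fine <- Reduce(`+`, Map(function(c, s) c * idx(s), w, -4:4)) / h
  coarse <- fine[seq(1, nf, by = over)]
  d_coarse <- spectral_derivative(coarse, delta)
  oracle <- d_fine[seq(1, nf, by = over)]
  rel_rms <- sqrt(mean((d_coarse - oracle)^2)) / sqrt(mean(oracle^2))
  expect_lt(rel_rms, 1e-6)
})

test_that("stability limit matches the leapfrog bound", {
  g3 <- grid_spec(1.3 / 6, c(32, 32, 32))
  # closed form 2 delta / (c pi sqrt(3)) evaluated once: 0.26563 fs
  expect_equal(stability_limit(g3, 1), 0.26563, tolerance = 1e-4)
  expect_true(0.252 <= stability_limit(g3, 1))
  g1 <- grid_spec(1.3 / 6, c(1, 1, 32))
  expect_equal(stability_limit(g1, 1) / stability_limit(g3, 1), sqrt(3),
               tolerance = 1e-12)
  expect_error(pstd_simulate(g1, nsteps = 2, dt = 2 * stability_limit(g1)),
               "stability")
})

test_that("zero fields with no source stay zero", {
  g <- grid_1d(48, pml = 0)
  st <- new_field_state(g)
  st2 <- step_fields(step_fields(st, g), g)
  expect_true(all(st2$Ex == 0) && all(st2$Hy == 0))
  expect_identical(st2$t_index, 2L)
})

test_that("pulses travel at c and c/1.42 within 1 percent", {
  speed_err <- function(nmed) {
    nz <- 540
    g <- grid_spec(lam0 / 6, c(1, 1, nz), pml_thickness = 10,
                   background_index = nmed)
    src <- plane_source_1d(15)
    dt <- 0.35 * stability_limit(g, n_min = 1)
    v <- C_UM_FS / nmed
    p1 <- 120L; p2 <- 470L
    ns <- ceiling((src$t0 + (p2 - src$z_index) * g$cell_size / v + 6 * src$W) / dt)
    out <- pstd_simulate(g, n = array(nmed, g$dims), source = src,
                         nsteps = ns, dt = dt,
                         ts_points = rbind(c(1, 1, p1), c(1, 1, p2)))
    t1e <- src$t0 + (p1 - src$z_index) * g$cell_size / v
    t2e <- src$t0 + (p2 - src$z_index) * g$cell_size / v
    t1 <- pulse_centroid(out$tsEx[, 1], dt, t1e, 5 * src$W)
    t2 <- pulse_centroid(out$tsEx[, 2], dt, t2e, 5 * src$W)
    (p2 - p1) * g$cell_size / (t2 - t1) / v - 1
  }
  expect_lt(abs(speed_err(1)), 0.01)
  expect_lt(abs(speed_err(1.42)), 0.01)
})

test_that("discrete energy is conserved in a periodic vacuum", {
  g <- grid_1d(128, pml = 0)
  src <- plane_source_1d(10, W = 6, t0 = 2.2 * 6)
  dt <- 0.9 * stability_limit(g)
  seed <- pstd_simulate(g, source = src, nsteps = ceiling((src$t0 + 4 * 6) / dt),
                        dt = dt, return_fields = TRUE)
  free <- pstd_simulate(g, nsteps = 1000, dt = dt, init = seed$fields,
                        energy_trace = TRUE)
  expect_lt(max(abs(free$energy / free$energy[1] - 1)), 1e-6)
})

test_that("solver response is linear in the source", {
  g <- grid_1d(96)
  run <- function(amp_x, amp_y) {
    src <- source_spec(14, matrix(amp_x, 1, 1), matrix(amp_y, 1, 1),
                       k0 = k0, W = 6, t0 = 14)
    pstd_simulate(g, source = src, nsteps = 250,
                  dt = 0.5 * stability_limit(g),
                  ts_points = matrix(c(1, 1, 60), 1))
  }
  a <- run(1 + 0i, 0i)
  b <- run(0i, 1 + 0i)
  ab <- run(2 + 0i, 3 + 0i)
  # Ey sources do not excite Ex in 1D, so superposition reduces to scaling
  expect_lt(max(abs(ab$tsEx - 2 * a$tsEx)), 1e-10 * max(abs(ab$tsEx)))
  expect_lt(max(abs(ab$tsHy - 2 * a$tsHy)), 1e-10 * max(abs(ab$tsHy)))
})

test_that("sheet source emits symmetrically and k_hat flips the sign", {
  g <- grid_1d(192, pml = 0)
  zc <- 96L
  mk <- function(k_hat) source_spec(zc, matrix(1 + 0i, 1, 1),
                                    matrix(0i, 1, 1), k0 = k0, W = 6,
                                    t0 = 14, k_hat = k_hat)
  dt <- 0.5 * stability_limit(g)
  d <- 40L
  fwd <- pstd_simulate(g, source = mk(1), nsteps = 400, dt = dt,
                       ts_points = rbind(c(1, 1, zc + d), c(1, 1, zc - d)))
  rev <- pstd_simulate(g, source = mk(-1), nsteps = 400, dt = dt,
                       ts_points = rbind(c(1, 1, zc + d), c(1, 1, zc - d)))
  # the magnetic current sheet radiates an antisymmetric E field: the pulse
  # magnitude mirrors about the source plane with opposite sign
  expect_lt(max(abs(fwd$tsEx[, 1] + fwd$tsEx[, 2])),
            1e-10 * max(abs(fwd$tsEx)))
  # reversing k_hat negates the sheet current and hence the field
  expect_lt(max(abs(rev$tsEx + fwd$tsEx)), 1e-10 * max(abs(fwd$tsEx)))
})

test_that("source waveform has the configured envelope and spectrum", {
  W <- source_envelope_width()   # band 1180-1420 nm
  src <- source_spec(5, matrix(1 + 0i, 1, 1), matrix(0i, 1, 1),
                     k0 = k0, W = W)
  j0 <- inject_source_waveform(src, 0)
  jpk <- inject_source_waveform(src, src$t0)
  expect_lt(max(abs(j0$Jy)), 1e-6 * max(abs(jpk$Jy)))
  # envelope factor exactly 1 at t = t0 (carrier phase 1 there too)
  expect_equal(abs(jpk$Jy[1, 1]), 1)
  # amplitude spectrum of the emitted waveform >= 10% of peak at band edges
  dt <- 0.05
  tt <- seq(0, 2 * src$t0, by = dt)
  jt <- vapply(tt, function(t) inject_source_waveform(src, t)$Jy[1, 1],
               numeric(1))
  om <- 2 * pi * C_UM_FS / c(1.18, 1.42)
  spec <- vapply(om, function(w) abs(sum(jt * exp(1i * w * tt)) * dt),
                 numeric(1))
  peak <- abs(sum(jt * exp(1i * src$omega0 * tt)) * dt)
  # W is chosen for >= 10% at both edges; allow time-window truncation
  # error of the numerical transform at the exact boundary
  expect_true(all(spec >= 0.098 * peak))
  expect_error(source_spec(5, matrix(1 + 0i, 1, 1), matrix(0i, 1, 1),
                           k0 = k0, W = W, t0 = W), "t0")
})

test_that("running DFT accumulation equals post-hoc Fourier analysis", {
  g <- grid_1d(128)
  src <- plane_source_1d(14, W = 6, t0 = 14)
  dt <- 0.5 * stability_limit(g)
  ks <- seq(2 * pi / 1.42, 2 * pi / 1.18, length.out = 7)
  pt <- c(1L, 1L, 70L)
  out <- pstd_simulate(g, source = src, nsteps = 600, dt = dt,
                       wavenumbers = ks, probe_points = matrix(pt, 1),
                       ts_points = matrix(pt, 1))
  tt <- seq_len(600) * dt
  posthoc <- vapply(C_UM_FS * ks,
                    function(w) sum(out$tsEx[, 1] * exp(1i * w * tt)) * dt,
                    complex(1))
  expect_lt(max(Mod(out$probe_E[1, , 1] - posthoc)),
            1e-10 * max(Mod(posthoc)))

  # R-level accumulator reproduces the same quantity
  pr <- spectral_probe(ks)
  for (i in seq_len(600)) pr <- accumulate_spectrum(pr, out$tsEx[i, 1], tt[i], dt)
  expect_lt(max(Mod(pr$acc[1, ] - posthoc)), 1e-12 * max(Mod(posthoc)))
  expect_warning(finalize_probe(pr, src, expected_steps = 700), "incomplete")
})

test_that("spectral probe obeys orthogonality and zero-field limits", {
  # monochromatic signal accumulated over an integer number of periods
  # vanishes at a different frequency on the period lattice
  T0 <- 100
  m1 <- 6; m2 <- 9
  w1 <- 2 * pi * m1 / T0; w2 <- 2 * pi * m2 / T0
  nsteps <- 1000
  dt <- T0 / nsteps   # accumulation spans exactly one lattice period
  pr <- spectral_probe(c(w1, w2) / C_UM_FS)
  tt <- (seq_len(nsteps)) * dt
  for (i in seq_len(nsteps)) {
    pr <- accumulate_spectrum(pr, exp(-1i * w1 * tt[i]), tt[i], dt)
  }
  expect_lt(Mod(pr$acc[1, 2]), 1e-10 * Mod(pr$acc[1, 1]))
  pr0 <- spectral_probe(c(w1, w2) / C_UM_FS)
  for (i in 1:10) pr0 <- accumulate_spectrum(pr0, 0 + 0i, tt[i], dt)
  expect_true(all(Mod(pr0$acc) == 0))
})

test_that("absorbing boundary meets its reflection targets", {
  g <- grid_1d(260)
  r10 <- measure_pml_reflection(g)
  expect_lt(r10, 1e-2)   # <= -40 dB power
  g0 <- grid_1d(260, pml = 0)
  expect_gt(measure_pml_reflection(g0), 0.5)  # wraparound, no absorber
  g20 <- grid_1d(300, pml = 20)
  expect_lte(measure_pml_reflection(g20), r10 * 1.5)  # thicker not worse
})

test_that("nyquist check and divergence detection fire", {
  g <- grid_spec(1.3 / 6, c(1, 1, 64))
  expect_error(check_nyquist(g, 1.18, 2.75), "undersampled")
  expect_silent(check_nyquist(g, 1.18, 2.609))
})
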