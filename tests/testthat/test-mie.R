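test_that("index-matched sphere scatters nothing", {
  sp <- sphere_spec(1, 1.42, 1.42, 1e-3)
  mie <- mie_coefficients(sp, 1.3)
  expect_true(all(Mod(mie$a) == 0) && all(Mod(mie$b) == 0))
  expect_equal(scattering_cross_section(mie), 0)
  expect_equal(asymmetry_parameter(mie), 0)
})

test_that("small-sphere limit matches Rayleigh theory", {
  # x = 0.01: Q_s -> (8/3) x^4 |(m^2-1)/(m^2+2)|^2
  m <- 2.609 / 1.42
  lam <- 1.3
  d <- 0.01 * lam / (pi * 1.42)
  sp <- sphere_spec(d, 2.609, 1.42)
  mie <- mie_coefficients(sp, lam)
  qs <- scattering_cross_section(mie) / (pi * (d / 2)^2)
  q_ray <- (8 / 3) * mie$x^4 * Mod((m^2 - 1) / (m^2 + 2))^2
  expect_lt(abs(qs / q_ray - 1), 0.01)
  expect_lt(abs(asymmetry_parameter(mie)), 0.01)

  # lambda^-4 scaling of sigma_s deep in the Rayleigh regime
  d2 <- 0.04 * 1.0 / (pi * 1.42)   # x = 0.04 at 1.0 um
  s1 <- scattering_cross_section(mie_coefficients(sphere_spec(d2, 2.609, 1.42), 1.0))
  s2 <- scattering_cross_section(mie_coefficients(sphere_spec(d2, 2.609, 1.42), 1.25))
  expect_lt(abs(s1 / s2 / (1.25 / 1.0)^4 - 1), 0.02)
})

test_that("coefficients agree with an independent recurrence", {
  for (m in c(1.1, 1.5, 1.84)) {
    for (x in c(0.5, 3.4, 10)) {
      n_med <- 1.42
      lam <- 1.3
      d <- x * lam / (pi * n_med)
      mie <- mie_coefficients(sphere_spec(d, m * n_med, n_med), lam)
      orc <- mie_oracle(m, x)
      n <- seq_len(min(mie$n_max, length(orc$a)))
      expect_lt(max(Mod(mie$a[n] - orc$a[n])), 1e-6)
      expect_lt(max(Mod(mie$b[n] - orc$b[n])), 1e-6)
      qs <- scattering_cross_section(mie) / (pi * (d / 2)^2)
      expect_lt(abs(qs / orc$qsca - 1), 1e-6)
      expect_lt(abs(asymmetry_parameter(mie) - orc$g), 1e-6)
    }
  }
})

test_that("optical theorem holds for the lossless sphere", {
  mie <- mie_coefficients(sphere_spec(1, 2.609, 1.42), 1.3)
  ext <- extinction_cross_section(mie)
  sca <- scattering_cross_section(mie)
  expect_lt(abs(ext / sca - 1), 1e-8)
  # forward-amplitude route: Q_ext = (4/x^2) Re S(0)
  s0 <- mie_amplitudes(mie, 0)
  q_fwd <- (4 / mie$x^2) * Re(s0$S1)
  expect_lt(abs(q_fwd / (ext / (pi * 0.25)) - 1), 1e-8)
})

test_that("asymmetry parameter equals phase-function quadrature", {
  mie <- mie_coefficients(sphere_spec(1, 2.609, 1.42), 1.3)
  th <- seq(0, pi, length.out = 8001)
  p <- mie_phase_function(mie, th)
  w <- sin(th)
  g_quad <- sum(p * cos(th) * w) / sum(p * w)
  expect_lt(abs(g_quad - asymmetry_parameter(mie)), 1e-6)
  expect_gt(asymmetry_parameter(mie), 0)  # forward scattering at x ~ 3.4
})

test_that("exterior fields conserve scattered power and match the far field", {
  mie <- mie_coefficients(sphere_spec(1, 2.609, 1.42), 1.3)
  quad_sphere <- function(R, nth = 90, nph = 180) {
    th <- (seq_len(nth) - 0.5) * pi / nth
    ph <- (seq_len(nph) - 0.5) * 2 * pi / nph
    gr <- expand.grid(th = th, ph = ph)
    list(pts = cbind(R * sin(gr$th) * cos(gr$ph),
                     R * sin(gr$th) * sin(gr$ph), R * cos(gr$th)),
         w = R^2 * sin(gr$th) * (pi / nth) * (2 * pi / nph),
         costh = cos(gr$th))
  }
  q <- quad_sphere(1.5)
  f <- exterior_fields(mie, q$pts)
  S <- poynting(f$E_sca, f$H_sca)
  flux <- sum(rowSums(S * (q$pts / 1.5)) * q$w)
  expect_lt(abs(flux / 0.5 / scattering_cross_section(mie) - 1), 0.005)

  # index-matched sphere: total Poynting equals the incident plane wave's
  mie1 <- mie_coefficients(sphere_spec(1, 1.42, 1.42), 1.3)
  f1 <- exterior_fields(mie1, q$pts)
  S1 <- poynting(f1$E_tot, f1$H_tot)
  expect_lt(max(abs(sweep(S1, 2, c(0, 0, 0.5)))), 1e-12)

  # far zone: radial Poynting proportional to the phase function
  kr <- 1e3
  R <- kr / mie$k_med
  qf <- quad_sphere(R, nth = 60, nph = 1)
  ff <- exterior_fields(mie, qf$pts)
  Sf <- poynting(ff$E_sca, ff$H_sca)
  rad <- rowSums(Sf * (qf$pts / R))
  th <- (seq_len(60) - 0.5) * pi / 60
  # at phi = 0 the scattered intensity follows |S2|^2 (in-plane polarization)
  p <- Mod(mie_amplitudes(mie, th)$S2)^2
  ratio <- rad / p
  expect_lt(stats::sd(ratio) / mean(ratio), 0.01)

  expect_error(exterior_fields(mie, matrix(c(0, 0, 0.2), 1)), "outside")
})

test_that("scattering coefficient scales linearly with concentration", {
  sp0 <- sphere_spec(1, 2.609, 1.42, 0)
  expect_equal(scattering_coefficient(sp0, 1.3), 0)
  sp1 <- sphere_spec(1, 2.609, 1.42, 2e-3)
  sp2 <- sphere_spec(1, 2.609, 1.42, 4e-3)
  expect_equal(2 * scattering_coefficient(sp1, 1.3),
               scattering_coefficient(sp2, 1.3))
})

test_that("spectrum weighting reduces to the expected limits", {
  sp <- sphere_spec(1, 2.609, 1.42, 4.5e-3)
  k <- seq(2 * pi / 1.42, 2 * pi / 1.18, length.out = 41)
  # delta spectrum at lambda0
  w <- rep(0, 41); w[21] <- 1
  expect_equal(spectrum_weighted_mu_s(sp, k, w),
               scattering_coefficient(sp, 2 * pi / k[21]))
  # flat spectrum = unweighted mean
  mu_each <- vapply(2 * pi / k, function(l) scattering_coefficient(sp, l),
                    numeric(1))
  expect_equal(spectrum_weighted_mu_s(sp, k, rep(1, 41)), mean(mu_each))
  expect_error(spectrum_weighted_mu_s(sp, k, rep(0, 41)), "weight")
})
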