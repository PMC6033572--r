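test_that("overlap coupling is the unconjugated transverse product", {
  set.seed(7)
  mk <- function() list(ex = matrix(complex(real = rnorm(64),
                                            imaginary = rnorm(64)), 8, 8),
                        ey = matrix(complex(real = rnorm(64),
                                            imaginary = rnorm(64)), 8, 8))
  ill <- mk(); f <- mk(); g <- mk()
  # linearity in the total field
  a <- 1.3 - 0.4i; b <- -0.2 + 2i
  comb <- list(ex = a * f$ex + b * g$ex, ey = a * f$ey + b * g$ey)
  lhs <- overlap_coupling(ill, comb, 0.2)
  rhs <- a * overlap_coupling(ill, f, 0.2) + b * overlap_coupling(ill, g, 0.2)
  expect_lt(Mod(lhs - rhs), 1e-12 * Mod(lhs))
  # no-sample identity feeds zero into the interference term
  a_tot <- overlap_coupling(ill, ill, 0.2)
  a_ill <- overlap_coupling(ill, ill, 0.2)
  expect_identical(a_tot - a_ill, 0 + 0i)
  bad <- list(ex = f$ex[1:4, ], ey = f$ey[1:4, ])
  expect_error(overlap_coupling(ill, bad, 0.2), "different grids")
})

test_that("interference power follows the printed combination", {
  k <- seq(4.4, 5.3, length.out = 16)
  set.seed(1)
  z <- function() complex(real = rnorm(16), imaginary = rnorm(16))
  at <- z(); ar <- z(); ai <- z()
  cs <- coupling_spectrum(k, at, ar, ai)
  expect_equal(interference_power(cs), Mod(at - ai + ar - ai)^2)
  # sample-only term: alpha_tot = alpha_ill leaves the reference spectrum
  expect_equal(interference_power(coupling_spectrum(k, ai, ar, ai)),
               Mod(ar - ai)^2)
  # swapping sample and reference terms leaves i(k) unchanged
  expect_equal(interference_power(coupling_spectrum(k, ar, at, ai)),
               interference_power(cs))
  # all equal -> dark fringe
  expect_equal(interference_power(coupling_spectrum(k, ai, ai, ai)),
               rep(0, 16))
})

test_that("shot noise is Poisson with the configured mean", {
  det <- detector_model(eta = 0, seed = 3)
  expect_equal(apply_shot_noise(rep(5, 10), det), rep(0, 10))
  expect_error(apply_shot_noise(c(-1, 1), det), "non-negative")
  det2 <- detector_model(eta = 1, seed = 11)
  draws <- apply_shot_noise(rep(1e3, 1e4), det2)
  se <- sqrt(1e3 / 1e4)
  expect_lt(abs(mean(draws) - 1e3), 3 * se)
  vm <- stats::var(draws) / mean(draws)
  expect_gt(vm, 0.95); expect_lt(vm, 1.05)
})

test_that("A-scan reconstruction has the expected Fourier structure", {
  n_k <- 512
  kk <- seq(2 * pi / 1.42, 2 * pi / 1.18, length.out = n_k)
  det_h <- detector_model(1, window = "hann")
  det_n <- detector_model(1, window = "none")
  # flat spectrum: |A| is the axial PSF, peaked at zero depth
  a0 <- reconstruct_ascan(rep(1, n_k), kk, det_h)
  expect_equal(a0$z[which.max(Mod(a0$A))], 0, tolerance = 1e-9)
  # Hanning window: first sidelobe at or below -31 dB (oversampled so the
  # sidelobes are not hidden at the transform's natural zeros)
  dk <- diff(kk)[1]
  zf <- seq(0, 40 * pi / (2 * dk) / n_k, length.out = 2000)
  proff <- Mod(reconstruct_ascan(rep(1, n_k), kk, det_h, z = zf)$A)
  pkv <- max(proff)
  first_null <- which(diff(proff) > 0)[1]
  sidelobe <- max(proff[(first_null + 1):length(proff)])
  expect_lte(20 * log10(sidelobe / pkv), -31)
  expect_gte(20 * log10(sidelobe / pkv), -45)   # it is a Hann, not stronger
  # cosine modulation: dominant side peak at the modulation depth
  d <- 30
  a1 <- reconstruct_ascan(1 + cos(2 * kk * d), kk, det_h)
  away <- abs(a1$z) > 10
  zpk <- a1$z[away][which.max(Mod(a1$A[away]))]
  dz <- diff(a1$z)[1]
  expect_lte(abs(abs(zpk) - d), dz)
  # Parseval (no window, natural conjugate grid)
  nt <- rnorm(n_k)^2
  a2 <- reconstruct_ascan(nt, kk, det_n)
  dk <- diff(kk)[1]
  lhs <- sum(Mod(a2$A)^2)
  rhs <- (dk / (2 * pi))^2 * n_k * sum(nt^2)
  expect_lt(abs(lhs / rhs - 1), 1e-8)
  # axial scaling by the group index
  a3 <- reconstruct_ascan(rep(1, n_k), kk, det_h, n_group = 1.42)
  expect_equal(a3$z * 1.42, a3$z_optical)
  expect_error(reconstruct_ascan(rep(1, 4), kk[c(1, 2, 4, 8)], det_h),
               "uniform")
})

test_that("eta calibration hits a target SNR and scales as shot noise", {
  n_k <- 256
  kk <- seq(2 * pi / 1.42, 2 * pi / 1.18, length.out = n_k)
  set.seed(5)
  # synthetic sample: a few reflectors at moderate depth over a dark band
  d <- c(40, 55, 70)
  i_k <- Mod(1.5 + 0.15 * exp(1i * 2 * kk %o% d) %*% rep(1, 3))^2
  i_list <- replicate(6, i_k, simplify = FALSE)
  sigr <- c(30, 80); noir <- c(150, 260)
  det <- calibrate_eta(i_list, kk, target_snr_db = 25, signal_range = sigr,
                       noise_range = noir, detector = detector_model(1, seed = 2))
  snr <- local({
    asc <- lapply(seq_along(i_list), function(j) {
      dj <- det; dj$seed <- det$seed + j
      reconstruct_ascan(apply_shot_noise(i_list[[j]], dj), kk, dj)
    })
    roi_snr_db(asc, sigr, noir)
  })
  expect_lt(abs(snr - 25), 0.3)
  # monotone non-decreasing in eta (three points)
  snr_at <- function(eta) {
    dj <- detector_model(eta, seed = 9)
    asc <- reconstruct_ascan(apply_shot_noise(i_k, dj), kk, dj)
    roi_snr_db(asc, sigr, noir)
  }
  s3 <- vapply(c(det$eta / 16, det$eta, det$eta * 16), snr_at, numeric(1))
  expect_true(all(diff(s3) > 0))
  # doubling eta in the shot-noise limit raises SNR by ~3 dB
  s2 <- vapply(c(det$eta * 32, det$eta * 64), snr_at, numeric(1))
  expect_lt(abs((s2[2] - s2[1]) - 10 * log10(2)), 0.5)
  # eta -> infinity approaches the noise-free reconstruction
  noisefree <- reconstruct_ascan(i_k, kk, detector_model(1))
  relrms <- vapply(c(1e6, 1e9), function(eta) {
    dj <- detector_model(eta, seed = 4)
    a <- reconstruct_ascan(apply_shot_noise(i_k, dj), kk, dj)
    sqrt(mean(Mod(a$A / eta - noisefree$A)^2)) / sqrt(mean(Mod(noisefree$A)^2))
  }, numeric(1))
  expect_lt(relrms[2], relrms[1])
  expect_error(calibrate_eta(i_list, kk, 500, sigr, noir,
                             detector_model(1), log_eta_range = c(-2, 2)),
               "calibration failure")
})

test_that("a mirror sample reconstructs at its optical depth", {
  # 1D end-to-end: PEC mirror sample below the reference-mirror plane
  cs <- lam0 / 6
  nz <- 300
  nprof <- rep(1.42, nz)
  mirror_ref <- 60L
  mirror_sample <- 140L
  ks <- seq(2 * pi / 1.42, 2 * pi / 1.18, length.out = 128)
  sample_prof <- nprof
  cpl_mirror <- oct_coupling_1d(sample_prof, cs, ks, mirror_z = mirror_ref,
                                W = 10, run_time_factor = 1.3)
  # sample run: replace alpha_tot by a run with the sample mirror
  cpl_sample <- oct_coupling_1d(sample_prof, cs, ks, mirror_z = mirror_sample,
                                W = 10, run_time_factor = 1.3)
  cpl <- coupling_spectrum(ks, alpha_tot = cpl_sample$alpha_ref,
                           alpha_ref = cpl_mirror$alpha_ref,
                           alpha_ill = cpl_mirror$alpha_ill)
  i_k <- interference_power(cpl)
  det <- detector_model(1, window = "hann")
  asc <- reconstruct_ascan(i_k, ks, det)
  opd <- optical_depth(sample_prof, cs, mirror_sample, mirror_ref)
  dzs <- diff(asc$z)[1]
  away <- abs(asc$z) > 10                # exclude the DC autocorrelation
  zpk <- asc$z[away][which.max(Mod(asc$A[away]))]
  expect_lte(abs(abs(zpk) - opd), dzs)
  # noise-free background far from the peak, its sidelobes and DC: -60 dB
  bg <- abs(asc$z) > 30 & abs(abs(asc$z) - opd) > 30
  expect_lt(20 * log10(max(Mod(asc$A[bg])) / max(Mod(asc$A[away]))), -60)
})
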