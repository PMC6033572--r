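# shared fixtures: small grids and cheap run settings used across tests

lam0 <- 1.3
k0 <- 2 * pi / lam0

# 1D grid factory
grid_1d <- function(nz, pml = 10, n_bg = 1, cell = lam0 / 6) {
  grid_spec(cell, c(1, 1, nz), pml_thickness = pml, background_index = n_bg)
}

# uniform plane source for 1D runs
plane_source_1d <- function(z_index, W = 8, t0 = 2.3 * W, k = k0) {
  source_spec(z_index, matrix(1 + 0i, 1, 1), matrix(0i, 1, 1),
              k0 = k, W = W, t0 = t0)
}

# centroid arrival time of a pulse in a time series, within a window
pulse_centroid <- function(ts, dt, t_expect, halfwidth) {
  tt <- seq_along(ts) * dt
  w <- abs(tt - t_expect) < halfwidth
  sum(tt[w] * ts[w]^2) / sum(ts[w]^2)
}

# FWHM of a sampled positive profile by linear interpolation
profile_fwhm <- function(x, y) {
  y <- y / max(y)
  i <- which(y >= 0.5)
  lo <- min(i); hi <- max(i)
  x_lo <- stats::approx(y[c(lo - 1, lo)], x[c(lo - 1, lo)], 0.5)$y
  x_hi <- stats::approx(y[c(hi, hi + 1)], x[c(hi, hi + 1)], 0.5)$y
  x_hi - x_lo
}

# independent Mie oracle: upward Riccati-Bessel recurrences for both
# arguments, no logarithmic derivative (different algorithm from the
# package implementation)
mie_oracle <- function(m, x) {
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  rb <- function(arg, nmax) {
    n <- seq_len(nmax)
    psi <- sqrt(pi * arg / 2) * besselJ(arg, n + 0.5)
    chi <- -sqrt(pi * arg / 2) * besselY(arg, n + 0.5)
    psi_prev <- c(sin(arg), psi[-nmax])
    chi_prev <- c(cos(arg), chi[-nmax])
    dpsi <- psi_prev - n / arg * psi
    dchi <- chi_prev - n / arg * chi
    list(psi = psi, dpsi = dpsi, xi = complex(real = psi, imaginary = -chi),
         dxi = complex(real = dpsi, imaginary = -dchi))
  }
  o <- rb(x, nmax); i <- rb(m * x, nmax)
  a <- (m * i$psi * o$dpsi - o$psi * i$dpsi) /
    (m * i$psi * o$dxi - o$xi * i$dpsi)
  b <- (i$psi * o$dpsi - m * o$psi * i$dpsi) /
    (i$psi * o$dxi - m * o$xi * i$dpsi)
  n <- seq_len(nmax)
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  t1 <- sum(n[-nmax] * (n[-nmax] + 2) / (n[-nmax] + 1) *
              Re(a[-nmax] * Conj(a[-1]) + b[-nmax] * Conj(b[-1])))
  t2 <- sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- (4 / (x^2 * qsca)) * (t1 + t2)
  list(a = a, b = b, qsca = qsca, g = g)
}
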