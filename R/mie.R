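#' Sphere specification
#'
#' Describes a homogeneous dielectric sphere suspended in a homogeneous
#' medium, together with a number density used to convert cross-sections
#' into scattering coefficients under the independent-scattering assumption.
#'
#' @param diameter Sphere diameter in micrometres.
#' @param n_particle Refractive index of the sphere (dimensionless, >= 1).
#' @param n_medium Refractive index of the embedding medium.
#' @param concentration Number density in particles per cubic micrometre.
#' @return An object of class `sphere_spec`.
#' @export
sphere_spec <- function(diameter, n_particle, n_medium = 1.42,
                        concentration = 0) {
  stopifnot(diameter > 0, n_particle >= 1, n_medium >= 1, concentration >= 0)
  structure(list(diameter = diameter, n_particle = n_particle,
                 n_medium = n_medium, concentration = concentration),
            class = "sphere_spec")
}

spherical_jn <- function(n, x) sqrt(pi / (2 * x)) * besselJ(x, n + 0.5)
spherical_yn <- function(n, x) sqrt(pi / (2 * x)) * besselY(x, n + 0.5)
spherical_hn <- function(n, x) complex(real = spherical_jn(n, x),
                                       imaginary = spherical_yn(n, x))

#' Lorenz-Mie coefficients
#'
#' Computes the standard Lorenz-Mie expansion coefficients `a_n`, `b_n` of a
#' homogeneous sphere for a plane wave of the given vacuum wavelength. The
#' logarithmic derivative of the Riccati-Bessel function is obtained by
#' downward recurrence; the Riccati-Bessel functions of the exterior argument
#' by upward recurrence (stable for the real arguments used here).
#'
#' All wavelengths in this package are vacuum wavelengths; the size parameter
#' uses the in-medium wavelength, `x = pi * d * n_medium / lambda_vac`.
#'
#' @param sphere A [sphere_spec()].
#' @param lambda_vac Vacuum wavelength (micrometres).
#' @return An object of class `mie_solution` with fields `m`, `x`, `a`, `b`,
#'   `n_max`, `k_med` (in-medium wavenumber, rad/um).
#' @export
mie_coefficients <- function(sphere, lambda_vac) {
  stopifnot(inherits(sphere, "sphere_spec"), lambda_vac > 0)
  m <- sphere$n_particle / sphere$n_medium
  x <- pi * sphere$diameter * sphere$n_medium / lambda_vac
  n_max <- ceiling(x + 4 * x^(1/3) + 2)
  if (abs(m - 1) < .Machine$double.eps * 10) {
    return(structure(list(m = m, x = x,
                          a = rep(0i, n_max), b = rep(0i, n_max),
                          n_max = n_max,
                          k_med = 2 * pi * sphere$n_medium / lambda_vac,
                          sphere = sphere, lambda_vac = lambda_vac),
                     class = "mie_solution"))
  }
  mx <- m * x
  n_start <- max(n_max, ceiling(abs(mx))) + 16
  # D[k + 1] holds the logarithmic derivative D_k(mx); D_{n_start} = 0 seed
  D <- numeric(n_start + 1)
  for (n in seq(n_start, 1)) {
    D[n] <- n / mx - 1 / (D[n + 1] + n / mx)
  }
  if (!all(is.finite(D[seq_len(n_max + 1)]))) {
    stop("Mie logarithmic-derivative recurrence did not converge")
  }
  n <- seq_len(n_max)
  # Riccati-Bessel psi_n = x j_n(x), chi_n = -x y_n(x); psi_0 = sin, chi_0 = cos
  psi <- sqrt(pi * x / 2) * besselJ(x, n + 0.5)
  chi <- -sqrt(pi * x / 2) * besselY(x, n + 0.5)
  psi_prev <- c(sin(x), psi[-n_max])
  chi_prev <- c(cos(x), chi[-n_max])
  xi <- complex(real = psi, imaginary = -chi)
  xi_prev <- complex(real = psi_prev, imaginary = -chi_prev)
  Dn <- D[n + 1]
  da <- Dn / m + n / x
  db <- Dn * m + n / x
  a <- (da * psi - psi_prev) / (da * xi - xi_prev)
  b <- (db * psi - psi_prev) / (db * xi - xi_prev)
  structure(list(m = m, x = x, a = a, b = b, n_max = n_max,
                 k_med = 2 * pi * sphere$n_medium / lambda_vac,
                 sphere = sphere, lambda_vac = lambda_vac),
            class = "mie_solution")
}

#' Scattering cross-section of a sphere
#'
#' `sigma_s = (lambda_med^2 / 2 pi) * sum (2n+1) (|a_n|^2 + |b_n|^2)`.
#'
#' @param mie A [mie_coefficients()] result.
#' @return Cross-section in square micrometres.
#' @export
scattering_cross_section <- function(mie) {
  stopifnot(inherits(mie, "mie_solution"))
  n <- seq_len(mie$n_max)
  (2 * pi / mie$k_med^2) * sum((2 * n + 1) * (Mod(mie$a)^2 + Mod(mie$b)^2))
}

#' Extinction cross-section (lossless: equals scattering)
#' @param mie A [mie_coefficients()] result.
#' @return Cross-section in square micrometres.
#' @export
extinction_cross_section <- function(mie) {
  n <- seq_len(mie$n_max)
  (2 * pi / mie$k_med^2) * sum((2 * n + 1) * Re(mie$a + mie$b))
}

#' Asymmetry parameter g = <cos theta>
#'
#' Mean cosine of the scattering angle from the standard coefficient series.
#'
#' @param mie A [mie_coefficients()] result.
#' @return g in [-1, 1].
#' @export
asymmetry_parameter <- function(mie) {
  stopifnot(inherits(mie, "mie_solution"))
  a <- mie$a; b <- mie$b; N <- mie$n_max
  if (all(Mod(a) == 0 & Mod(b) == 0)) return(0)
  n <- seq_len(N - 1)
  t1 <- sum(n * (n + 2) / (n + 1) *
              Re(a[n] * Conj(a[n + 1]) + b[n] * Conj(b[n + 1])))
  n <- seq_len(N)
  t2 <- sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  qsca <- (2 / mie$x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  (4 / (mie$x^2 * qsca)) * (t1 + t2)
}

# angular functions pi_n, tau_n for mu = cos(theta); returns n_max x length(mu)
mie_pi_tau <- function(n_max, mu) {
  np <- length(mu)
  p <- matrix(0, n_max, np); t <- matrix(0, n_max, np)
  p_prev <- rep(0, np)   # pi_0
  p_cur <- rep(1, np)    # pi_1
  for (n in seq_len(n_max)) {
    p[n, ] <- p_cur
    t[n, ] <- n * mu * p_cur - (n + 1) * p_prev
    p_next <- ((2 * n + 1) / n) * mu * p_cur - ((n + 1) / n) * p_prev
    p_prev <- p_cur
    p_cur <- p_next
  }
  list(pi = p, tau = t)
}

#' Mie scattering amplitudes S1, S2
#'
#' @param mie A [mie_coefficients()] result.
#' @param theta Scattering angles (radians).
#' @return List with complex vectors `S1`, `S2`.
#' @export
mie_amplitudes <- function(mie, theta) {
  mu <- cos(theta)
  pt <- mie_pi_tau(mie$n_max, mu)
  n <- seq_len(mie$n_max)
  w <- (2 * n + 1) / (n * (n + 1))
  S1 <- as.vector(crossprod(pt$pi, w * mie$a) + crossprod(pt$tau, w * mie$b))
  S2 <- as.vector(crossprod(pt$tau, w * mie$a) + crossprod(pt$pi, w * mie$b))
  list(S1 = S1, S2 = S2)
}

#' Unpolarized phase function (unnormalized)
#'
#' Proportional to the scattered far-field intensity versus angle for
#' unpolarized (or azimuth-averaged) illumination.
#'
#' @param mie A [mie_coefficients()] result.
#' @param theta Scattering angles (radians).
#' @return Numeric vector, `(|S1|^2 + |S2|^2)/2`.
#' @export
mie_phase_function <- function(mie, theta) {
  s <- mie_amplitudes(mie, theta)
  (Mod(s$S1)^2 + Mod(s$S2)^2) / 2
}

#' Exterior electromagnetic fields of a sphere
#'
#' Evaluates incident, scattered and total E and H fields at exterior points
#' for an x-polarized unit plane wave travelling along +z, from the vector
#' spherical harmonic expansion with outgoing (Hankel) radial functions.
#' Fields are in units where the medium impedance is 1, so the incident
#' time-averaged Poynting vector is `(0, 0, 1/2)`.
#'
#' @param mie A [mie_coefficients()] result.
#' @param points Numeric matrix (n x 3) of positions relative to the sphere
#'   center, micrometres. All points must lie outside the sphere.
#' @return List with complex matrices `E_inc`, `H_inc`, `E_sca`, `H_sca`,
#'   `E_tot`, `H_tot` (n x 3, Cartesian).
#' @export
exterior_fields <- function(mie, points) {
  stopifnot(inherits(mie, "mie_solution"), is.matrix(points), ncol(points) == 3)
  r <- sqrt(rowSums(points^2))
  if (any(r <= mie$sphere$diameter / 2)) {
    stop("all evaluation points must lie outside the sphere")
  }
  k <- mie$k_med
  rho <- k * r
  theta <- acos(pmin(1, pmax(-1, points[, 3] / r)))
  phi <- atan2(points[, 2], points[, 1])
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(phi); sp <- sin(phi)

  np <- nrow(points); N <- mie$n_max
  pt <- mie_pi_tau(N, ct)

  Er <- Et <- Ep <- rep(0i, np)   # scattered field, spherical components
  Hr <- Ht <- Hp <- rep(0i, np)
  for (n in seq_len(N)) {
    zn <- spherical_hn(n, rho)
    znm1 <- if (n == 1) {
      complex(real = sin(rho) / rho, imaginary = -cos(rho) / rho)
    } else {
      spherical_hn(n - 1, rho)
    }
    dzeta <- rho * znm1 - n * zn          # d/drho [rho z_n(rho)]
    En <- (1i^n) * (2 * n + 1) / (n * (n + 1))
    pin <- pt$pi[n, ]; taun <- pt$tau[n, ]
    an <- mie$a[n]; bn <- mie$b[n]
    # E_s = sum En (i a_n N3_e1n - b_n M3_o1n)
    Er <- Er + En * (1i * an * cp * n * (n + 1) * st * pin * zn / rho)
    Et <- Et + En * (1i * an * cp * taun * dzeta / rho - bn * cp * pin * zn)
    Ep <- Ep + En * (-1i * an * sp * pin * dzeta / rho + bn * sp * taun * zn)
    # H_s = sum En (i b_n N3_o1n + a_n M3_e1n)   (impedance-normalized)
    Hr <- Hr + En * (1i * bn * sp * n * (n + 1) * st * pin * zn / rho)
    Ht <- Ht + En * (1i * bn * sp * taun * dzeta / rho - an * sp * pin * zn)
    Hp <- Hp + En * (1i * bn * cp * pin * dzeta / rho - an * cp * taun * zn)
  }
  # spherical -> Cartesian
  sph2cart <- function(vr, vt, vp) {
    cbind(vr * st * cp + vt * ct * cp - vp * sp,
          vr * st * sp + vt * ct * sp + vp * cp,
          vr * ct - vt * st)
  }
  E_sca <- sph2cart(Er, Et, Ep)
  H_sca <- sph2cart(Hr, Ht, Hp)
  ph <- exp(1i * k * points[, 3])
  E_inc <- cbind(ph, 0i * ph, 0i * ph)
  H_inc <- cbind(0i * ph, ph, 0i * ph)
  list(E_inc = E_inc, H_inc = H_inc, E_sca = E_sca, H_sca = H_sca,
       E_tot = E_inc + E_sca, H_tot = H_inc + H_sca)
}

#' Time-averaged Poynting vector from complex field phasors
#'
#' `S = Re(E x conj(H)) / 2`, rowwise for n x 3 complex matrices.
#'
#' @param E,H Complex n x 3 matrices.
#' @return Real n x 3 matrix.
#' @export
poynting <- function(E, H) {
  Hc <- Conj(H)
  0.5 * cbind(Re(E[, 2] * Hc[, 3] - E[, 3] * Hc[, 2]),
              Re(E[, 3] * Hc[, 1] - E[, 1] * Hc[, 3]),
              Re(E[, 1] * Hc[, 2] - E[, 2] * Hc[, 1]))
}

#' Scattering coefficient mu_s = rho * sigma_s
#'
#' Independent-scattering conversion of the Mie cross-section into a bulk
#' scattering coefficient at the given vacuum wavelength.
#'
#' @param sphere A [sphere_spec()] with a concentration.
#' @param lambda_vac Vacuum wavelength (micrometres).
#' @return mu_s in 1/mm.
#' @export
scattering_coefficient <- function(sphere, lambda_vac) {
  sig <- scattering_cross_section(mie_coefficients(sphere, lambda_vac))
  sphere$concentration * sig * 1e3   # um^-3 * um^2 = um^-1 -> mm^-1
}

#' Spectrum-weighted scattering coefficient
#'
#' Averages the Mie scattering cross-section over a sampled system spectrum
#' S(k) and converts to a bulk coefficient:
#' `mu_s_eff = rho * sum(S_m sigma_s(k_m)) / sum(S_m)`.
#'
#' @param sphere A [sphere_spec()].
#' @param wavenumbers Vacuum wavenumbers (rad/um) at which S is sampled.
#' @param weights Non-negative spectral weights S(k); normalized internally.
#' @return mu_s_eff in 1/mm.
#' @export
spectrum_weighted_mu_s <- function(sphere, wavenumbers, weights) {
  stopifnot(length(wavenumbers) == length(weights), all(weights >= 0))
  if (sum(weights) <= 0) stop("spectrum must have positive total weight")
  lam <- 2 * pi / wavenumbers
  sig <- vapply(lam, function(l)
    scattering_cross_section(mie_coefficients(sphere, l)), numeric(1))
  sphere$concentration * sum(weights * sig) / sum(weights) * 1e3
}
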