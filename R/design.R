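#' Symmetry-reduced discrete scatterer design
#'
#' A scatterer occupying a 7x7x7 bounding cube of grid cells whose
#' refractive indices are free parameters. Mirror symmetry about the three
#' orthogonal planes of cells bisecting the cube reduces the degrees of
#' freedom to the 4x4x4 non-negative-index octant: the index of cell
#' (i, j, k), i,j,k in -3..3, equals that of (|i|, |j|, |k|).
#'
#' @param params Numeric vector of 64 refractive indices (the octant values,
#'   ordered as an array with dims c(4,4,4): index 1 = offset 0).
#' @param cell_size Grid cell size (um).
#' @param bounds Allowed index range.
#' @return An object of class `scatterer_design`.
#' @export
scatterer_design <- function(params, cell_size, bounds = c(1, 3.5)) {
  stopifnot(length(params) == 64)
  if (any(params < bounds[1] - 1e-12) || any(params > bounds[2] + 1e-12)) {
    stop("design parameters outside the allowed index bounds")
  }
  structure(list(params = as.numeric(params), cell_size = cell_size,
                 bounds = bounds), class = "scatterer_design")
}

#' Expand octant parameters to the full 7^3 cube
#'
#' @param params 64 octant refractive indices (array order, dims c(4,4,4)).
#' @param bounds Validation bounds.
#' @return 7x7x7 array; element (i,j,k) with offsets -3..3 equals the octant
#'   value at (|i|,|j|,|k|).
#' @export
expand_symmetric <- function(params, bounds = c(1, 3.5)) {
  if (length(params) != 64) stop("expected exactly 64 octant values")
  if (any(params < bounds[1] - 1e-12) || any(params > bounds[2] + 1e-12)) {
    stop("parameter outside bounds")
  }
  oct <- array(params, c(4, 4, 4))
  idx <- abs(-3:3) + 1
  oct[idx, idx, idx]
}

#' Extract the octant parameters from a symmetric 7^3 cube
#'
#' Inverse of [expand_symmetric()].
#'
#' @param cube 7x7x7 array.
#' @return 64 octant values.
#' @export
octant_extract <- function(cube) {
  stopifnot(all(dim(cube) == 7))
  as.numeric(cube[4:7, 4:7, 4:7])
}

#' Stair-case discretizations of a sphere
#'
#' Three deliberately different discrete approximations of a sphere on a
#' cubic grid:
#' mode 1 - cells whose centers lie within the radius, sphere centered on a
#' cell center; mode 2 - the same test with the sphere centered on a cell
#' corner; mode 3 - cells at least half covered by the sphere (5^3 volume
#' subsampling), with the sphere centered on a cell face center (half-cell
#' offset along z). The three centerings guarantee mutually distinct
#' stair-case shapes at the micrometre-scale sphere sizes this models.
#'
#' @param diameter Sphere diameter (um).
#' @param cell_size Cell size (um).
#' @param mode 1, 2 or 3.
#' @return Integer matrix (n x 3) of cell offsets. For modes 1 and 3 offsets
#'   are relative to the center cell; for mode 2, relative to the cell whose
#'   corner carries the sphere center.
#' @export
discretize_sphere <- function(diameter, cell_size, mode = 1) {
  stopifnot(diameter > 0, cell_size > 0, mode %in% 1:3)
  if (cell_size > diameter) {
    warning("cell size exceeds the diameter: single-cell or empty result")
  }
  r <- diameter / 2
  m <- ceiling(r / cell_size) + 1
  off <- as.matrix(expand.grid(i = -m:m, j = -m:m, k = -m:m))
  centers <- switch(as.character(mode),
    "1" = off * cell_size,
    "2" = (off + 0.5) * cell_size,                        # corner-centered
    "3" = sweep(off * cell_size, 2, c(0, 0, 0.5 * cell_size), `+`))
  if (mode %in% c(1, 2)) {
    keep <- sqrt(rowSums(centers^2)) <= r
  } else {
    sub <- (seq_len(5) - 3) / 5 * cell_size
    subg <- as.matrix(expand.grid(sub, sub, sub))
    frac <- vapply(seq_len(nrow(off)), function(i) {
      pts <- sweep(subg, 2, centers[i, ], `+`)
      mean(rowSums(pts^2) <= r^2)
    }, numeric(1))
    keep <- frac >= 0.5
  }
  unname(off[keep, , drop = FALSE])
}

#' Refractive-index cube from a cell set
#'
#' Stamps scattering cells into a bounding cube of side `side` on a uniform
#' background.
#'
#' @param cells Integer offsets (n x 3) from [discretize_sphere()].
#' @param n_scatter Index of the scattering cells.
#' @param n_background Index elsewhere.
#' @param side Cube side in cells (odd; default 7).
#' @return side^3 array.
#' @export
design_cube_from_cells <- function(cells, n_scatter, n_background = 1.42,
                                   side = 7) {
  h <- (side - 1) / 2
  cube <- array(n_background, c(side, side, side))
  keep <- apply(abs(cells) <= h, 1, all)
  idx <- cells[keep, , drop = FALSE] + h + 1
  cube[idx] <- n_scatter
  cube
}

#' Closed cubic reference surface of triangular facets
#'
#' Triangulates the six faces of a cube of the given half-width with a
#' vertex lattice of the given spacing (two triangles per square patch),
#' computing per-facet areas and outward unit normals.
#'
#' @param half_width Cube half-width (um).
#' @param spacing Vertex spacing (um); `2 * half_width / spacing` must be a
#'   whole number.
#' @return An object of class `reference_surface`: `V` (nv x 3 vertices),
#'   `F` (nf x 3 vertex indices), `A` (facet areas), `nhat` (nf x 3 outward
#'   normals).
#' @export
build_reference_surface <- function(half_width, spacing) {
  m <- round(2 * half_width / spacing)
  stopifnot(m >= 1, abs(m * spacing - 2 * half_width) < 1e-9)
  u <- seq(-half_width, half_width, length.out = m + 1)
  vkey <- new.env(hash = TRUE)
  V <- matrix(0, 0, 3); F <- matrix(0L, 0, 3)
  getv <- function(p) {
    key <- paste(round(p / spacing * 2), collapse = ",")
    id <- vkey[[key]]
    if (is.null(id)) {
      V <<- rbind(V, p)
      id <- nrow(V)
      vkey[[key]] <- id
    }
    id
  }
  # in-plane axes in cyclic (right-handed) order so that the standard
  # counter-clockwise winding yields the +axis normal on the s = +1 face
  plane_axes <- list(c(2L, 3L), c(3L, 1L), c(1L, 2L))
  for (axis in 1:3) for (s in c(-1, 1)) {
    for (a in seq_len(m)) for (b in seq_len(m)) {
      corn <- list(c(u[a], u[b]), c(u[a + 1], u[b]),
                   c(u[a + 1], u[b + 1]), c(u[a], u[b + 1]))
      p3 <- lapply(corn, function(q) {
        p <- numeric(3); p[axis] <- s * half_width
        p[plane_axes[[axis]]] <- q
        p
      })
      ids <- vapply(p3, getv, integer(1))
      # wind both triangles so the normal points outward (+s along axis)
      tri <- if (s > 0) rbind(ids[c(1, 2, 3)], ids[c(1, 3, 4)])
             else rbind(ids[c(1, 3, 2)], ids[c(1, 4, 3)])
      F <- rbind(F, tri)
    }
  }
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  A <- 0.5 * sqrt(rowSums(cr^2))
  nhat <- cr / (2 * A)
  structure(list(V = unname(V), F = unname(F), A = A, nhat = nhat,
                 half_width = half_width, spacing = spacing),
            class = "reference_surface")
}

# facet-vertex quadrature: sum_f w(f) . (A_f/3) sum_{l in f} val(l)
# val: nv-vector (or nv x 3); returns per-facet scalar (dot with normal if 3d)
facet_normal_sum <- function(surface, val) {
  Fm <- surface$F
  if (is.matrix(val)) {
    s <- val[Fm[, 1], , drop = FALSE] + val[Fm[, 2], , drop = FALSE] +
      val[Fm[, 3], , drop = FALSE]
    rowSums(surface$nhat * s) * surface$A / 3
  } else {
    (val[Fm[, 1]] + val[Fm[, 2]] + val[Fm[, 3]]) * surface$A / 3
  }
}

#' Poynting-flux mismatch against a Mie target
#'
#' The spectrum-weighted, surface-integrated squared mismatch between the
#' discrete scatterer's vertex Poynting vectors and the Mie reference:
#' facet-vertex quadrature of the normal components, normalized by the
#' corresponding Mie quadrature, summed over wavelengths with weights
#' S(lambda_m).
#'
#' @param S_tilde Numeric array (nv x 3 x n_lambda): discrete-case vertex
#'   Poynting vectors.
#' @param S_mie Numeric array (nv x 3 x n_lambda): Mie-case vectors.
#' @param surface A [reference_surface()].
#' @param weights Spectral weights S(lambda_m).
#' @return Scalar mismatch epsilon.
#' @export
poynting_mismatch <- function(S_tilde, S_mie, surface, weights) {
  nv <- nrow(surface$V)
  if (!all(dim(S_tilde)[1:2] == c(nv, 3)) ||
      !all(dim(S_mie)[1:2] == c(nv, 3))) {
    stop("vertex count of Poynting arrays does not match the surface")
  }
  nl <- dim(S_tilde)[3]
  stopifnot(dim(S_mie)[3] == nl, length(weights) == nl)
  eps <- 0
  for (m in seq_len(nl)) {
    dnum <- facet_normal_sum(surface, S_tilde[, , m] - S_mie[, , m])
    dden <- facet_normal_sum(surface, S_mie[, , m])
    eps <- eps + weights[m] * sum(Mod(dnum)^2) / sum(Mod(dden)^2)
  }
  eps
}

#' Mie vertex Poynting vectors for a design target
#'
#' Total-field (incident + scattered) time-averaged Poynting vectors at the
#' reference-surface vertices, normalized to unit incident intensity.
#'
#' @param sphere A [sphere_spec()].
#' @param surface A [reference_surface()].
#' @param lambdas Vacuum wavelengths (um).
#' @return Array nv x 3 x length(lambdas).
#' @export
mie_vertex_poynting <- function(sphere, surface, lambdas) {
  nv <- nrow(surface$V)
  out <- array(0, c(nv, 3, length(lambdas)))
  for (m in seq_along(lambdas)) {
    mie <- mie_coefficients(sphere, lambdas[m])
    f <- exterior_fields(mie, surface$V)
    out[, , m] <- poynting(f$E_tot, f$H_tot) / 0.5
  }
  out
}

# ---- plane-wave PSTD workbench -------------------------------------------

#' Build the grid geometry for a plane-wave scattering run
#'
#' Lays out an x-polarized, +z plane-wave run: absorber on all faces, a
#' full-width source plane above the scatterer, the scatterer bounding cube
#' centered, and a cubic reference surface of vertices on cell centers.
#'
#' @param cell_size Cell size (um).
#' @param scatterer_half Scatterer half-extent in cells (3 for a 7^3 cube).
#' @param surface_margin Cells between scatterer and surface (default 5).
#' @param pml_thickness Absorber cells per face.
#' @param medium_index Embedding medium index.
#' @param lambda0 Central vacuum wavelength (um); sets the clearance between
#'   the reference surface and the absorber. The absorber damps reactive
#'   near fields it touches, so this clearance must scale with wavelength
#'   (0.7 lambda0 by default), not with cell count.
#' @return List with the grid, center indices, source plane index, the
#'   reference surface, and its vertex cell indices.
#' @export
scatter_geometry <- function(cell_size, scatterer_half = 3,
                             surface_margin = 5, pml_thickness = 10,
                             medium_index = 1.42, lambda0 = 1.3,
                             clearance_cells = NULL) {
  hw <- scatterer_half + surface_margin
  margin <- if (is.null(clearance_cells)) {
    max(3, ceiling(0.7 * lambda0 / cell_size))
  } else {
    clearance_cells
  }
  nxy <- fft_good_size(2 * (hw + margin + pml_thickness) + 1)
  src_z <- pml_thickness + 3   # retained for grid layouts that inject a sheet
  cz <- pml_thickness + margin + hw + 1
  nz <- fft_good_size(cz + hw + margin + pml_thickness)
  g <- grid_spec(cell_size, c(nxy, nxy, nz), pml_thickness = pml_thickness,
                 background_index = medium_index)
  ctr <- c(ceiling(nxy / 2), ceiling(nxy / 2), cz)
  surf <- build_reference_surface(hw * cell_size, cell_size)
  vidx <- sweep(round(surf$V / cell_size), 2, ctr, `+`)
  storage.mode(vidx) <- "integer"
  list(grid = g, center = ctr, src_z = src_z, surface = surf,
       vertex_idx = vidx, hw = hw)
}

#' Run a plane-wave scattering simulation and return vertex spectra
#'
#' Scattered-field formulation: the solver advances the scattered field
#' directly, driven by the contrast source
#' `-((eps - eps_bg)/eps) dE_inc/dt` inside the scatterer cells, where
#' `E_inc` is an analytic x-polarized plane-wave pulse travelling along +z
#' at the medium phase velocity. The incident wave therefore never exists on
#' the grid (it is exact and perfectly uniform), the absorber only sees
#' outgoing scattered waves, and no homogeneous reference run is required.
#'
#' @param geom A [scatter_geometry()].
#' @param n_cube Refractive-index cube of the scatterer (odd side).
#' @param wavenumbers Vacuum wavenumbers (rad/um) to probe.
#' @param W Source envelope width (fs).
#' @param run_time_factor Run length multiplier (settling margin).
#' @param reference Unused (kept for call compatibility; the scattered-field
#'   formulation has no reference run).
#' @param dt Time step; default 0.9 of the stability limit.
#' @return List with `E_sca`, `H_sca` (nv x nk x 3 complex, normalized per
#'   unit incident amplitude at the scatterer center), analytic `E_inc`,
#'   `H_inc` on the vertices, `I_inc` (incident intensity, = n/(2c)),
#'   `dt`, `nsteps`.
#' @export
plane_wave_scatter_run <- function(geom, n_cube, wavenumbers, W = 12,
                                   run_time_factor = 1.6, reference = NULL,
                                   dt = NULL) {
  g <- geom$grid
  nmed <- g$background_index
  if (is.null(dt)) dt <- 0.9 * stability_limit(g, n_min = 1)
  v <- C_UM_FS / nmed
  omega0 <- C_UM_FS * (2 * pi / 1.3)
  t0 <- 2.5 * W
  t_total <- t0 + run_time_factor * (g$dims[3] * g$cell_size / v + 6 * W)
  nsteps <- ceiling(t_total / dt)
  nv <- nrow(geom$vertex_idx)

  # contrast-source cells
  side <- dim(n_cube)[1]
  h <- (side - 1) / 2
  eps_bg <- nmed^2
  coef <- (n_cube^2 - eps_bg) / n_cube^2
  active <- which(abs(coef) > 0)
  out <- NULL
  if (length(active) == 0) {
    # contrast-free: nothing scatters
    zero <- array(0i, c(nv, length(wavenumbers), 3))
    run <- list(E = zero, H = zero, dt = dt, nsteps = nsteps)
  } else {
    offs <- arrayInd(active, dim(coef)) - (h + 1)
    cells <- sweep(offs, 2, geom$center, `+`)
    lin <- (cells[, 1] - 1) + g$dims[1] * (cells[, 2] - 1) +
      g$dims[1] * g$dims[2] * (cells[, 3] - 1)
    sf <- list(idx = as.integer(lin), coef = coef[active],
               z_rel = offs[, 3] * g$cell_size, v = v,
               omega0 = omega0, t0 = t0, W = W)
    # the scattered field propagates in the true inhomogeneous medium
    n_arr <- array(nmed, g$dims)
    ii <- (geom$center[1] - h):(geom$center[1] + h)
    jj <- (geom$center[2] - h):(geom$center[2] + h)
    kk <- (geom$center[3] - h):(geom$center[3] + h)
    n_arr[ii, jj, kk] <- n_cube
    sim <- pstd_simulate(g, n = n_arr, nsteps = nsteps, dt = dt,
                         wavenumbers = wavenumbers,
                         probe_points = geom$vertex_idx, sf_source = sf)
    run <- list(E = sim$probe_E, H = sim$probe_H, dt = dt, nsteps = nsteps)
  }

  # analytic incident spectra at the vertices (the DFT of the real-valued
  # pulse at omega > 0): G(w, z) = (W/2) exp(i w t0) exp(i k_med z) *
  # exp(-(w - w0)^2 W^2 / (4 pi)), with z relative to the scatterer center
  omegas <- C_UM_FS * wavenumbers
  k_med <- omegas / v
  zoff <- (geom$vertex_idx[, 3] - geom$center[3]) * g$cell_size
  nk <- length(wavenumbers)
  G0 <- (W / 2) * exp(1i * omegas * t0) * exp(-(omegas - omega0)^2 * W^2 / (4 * pi))
  E_inc <- array(0i, c(nv, nk, 3)); H_inc <- array(0i, c(nv, nk, 3))
  E_sca <- array(0i, c(nv, nk, 3)); H_sca <- array(0i, c(nv, nk, 3))
  for (k in seq_len(nk)) {
    # unit incident amplitude at the scatterer center; solver spectra are
    # normalized by the analytic pulse spectrum G0
    E_inc[, k, 1] <- exp(1i * k_med[k] * zoff)
    H_inc[, k, 2] <- E_inc[, k, 1] * (nmed / C_UM_FS)
    E_sca[, k, ] <- run$E[, k, ] / G0[k]
    H_sca[, k, ] <- run$H[, k, ] / G0[k]
  }
  I_inc <- rep(0.5 * nmed / C_UM_FS, nk)
  list(E_sca = E_sca, H_sca = H_sca, E_inc = E_inc, H_inc = H_inc,
       I_inc = I_inc, reference = NULL, dt = dt, nsteps = nsteps)
}

#' Total-field vertex Poynting vectors of a discrete scatterer
#'
#' Runs the PSTD plane-wave workbench and returns the time-averaged
#' total-field Poynting vectors at the reference-surface vertices,
#' normalized to unit incident intensity (directly comparable with
#' [mie_vertex_poynting()]).
#'
#' @param n_cube Scatterer refractive-index cube.
#' @param geom A [scatter_geometry()].
#' @param wavenumbers Vacuum wavenumbers (rad/um).
#' @param ... Passed to [plane_wave_scatter_run()].
#' @return List: `S_tilde` (nv x 3 x nk array), `run` (the raw run).
#' @export
pstd_scattered_poynting <- function(n_cube, geom, wavenumbers, ...) {
  run <- plane_wave_scatter_run(geom, n_cube, wavenumbers, ...)
  nv <- dim(run$E_sca)[1]; nk <- dim(run$E_sca)[2]
  S <- array(0, c(nv, 3, nk))
  for (k in seq_len(nk)) {
    S[, , k] <- poynting(run$E_inc[, k, ] + run$E_sca[, k, ],
                         run$H_inc[, k, ] + run$H_sca[, k, ]) / run$I_inc[k]
  }
  list(S_tilde = S, run = run)
}

# far-field scattering pattern from equivalent surface currents
# (Stratton-Chu far zone); returns |E_far|^2 at directions (ndir x 3)
ntff_pattern <- function(surface, E_sca, H_sca, k_med, eta, dirs) {
  Fm <- surface$F; nf <- nrow(Fm)
  # facet quadrature: each facet contributes (A/3) sum over its vertices
  # accumulate per-vertex weights
  nv <- nrow(surface$V)
  wv <- numeric(nv)
  for (c in 1:3) {
    t <- tabulate(Fm[, c], nv)
    wv <- wv + t
  }
  # per-vertex area weight: sum of A/3 over facets sharing the vertex,
  # with the vertex's facet normal; normals vary per facet, so accumulate
  # weighted normals instead
  wn <- matrix(0, nv, 3)
  for (c in 1:3) {
    for (d in 1:3) {
      wn[, d] <- wn[, d] + unname(tapply(surface$A / 3 * surface$nhat[, d],
                                         factor(Fm[, c], levels = seq_len(nv)),
                                         sum, default = 0))
    }
  }
  wn[is.na(wn)] <- 0
  cross_rows <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  nxE <- cross_rows(wn, E_sca)   # area-weighted n x E per vertex
  nxH <- cross_rows(wn, H_sca)
  ndir <- nrow(dirs)
  pat <- numeric(ndir)
  ph <- exp(-1i * k_med * (surface$V %*% t(dirs)))  # nv x ndir
  for (d in seq_len(ndir)) {
    s <- dirs[d, ]
    Ne <- colSums(nxE * ph[, d])   # integral of (n x E) e^{-ik s.r'}
    Nh <- colSums(nxH * ph[, d])
    sxNe <- c(s[2] * Ne[3] - s[3] * Ne[2], s[3] * Ne[1] - s[1] * Ne[3],
              s[1] * Ne[2] - s[2] * Ne[1])
    sxNh <- c(s[2] * Nh[3] - s[3] * Nh[2], s[3] * Nh[1] - s[1] * Nh[3],
              s[1] * Nh[2] - s[2] * Nh[1])
    sxsxNh <- c(s[2] * sxNh[3] - s[3] * sxNh[2],
                s[3] * sxNh[1] - s[1] * sxNh[3],
                s[1] * sxNh[2] - s[2] * sxNh[1])
    # far-zone field direction: s x (n x E) - eta s x s x (n x H)
    Efar <- sxNe - eta * sxsxNh
    # remove any radial residue
    Efar <- Efar - s * sum(s * Efar)
    pat[d] <- sum(Mod(Efar)^2)
  }
  pat
}

#' Characterize a discrete scatterer: cross-section and asymmetry parameter
#'
#' Runs the plane-wave PSTD workbench: the scattering cross-section comes
#' from the net scattered-field Poynting flux through the reference surface
#' (scattered = total minus homogeneous-reference fields), and g from the
#' far-field pattern obtained by a surface-equivalence near-to-far-field
#' transform of the scattered fields.
#'
#' @param n_cube Scatterer refractive-index cube (odd side).
#' @param wavenumbers Vacuum wavenumbers (rad/um).
#' @param cell_size Grid cell size (um).
#' @param medium_index Embedding medium.
#' @param concentration Number density (um^-3) for mu_s.
#' @param geom Optional precomputed [scatter_geometry()].
#' @param n_theta,n_phi Far-field direction resolution for g.
#' @param ... Passed to [plane_wave_scatter_run()].
#' @return data.frame with lambda_um, sigma_s_um2, mu_s_mm, g.
#' @export
characterize_scatterer <- function(n_cube, wavenumbers, cell_size,
                                   medium_index = 1.42, concentration = 0,
                                   geom = NULL, n_theta = 24, n_phi = 48,
                                   ...) {
  side <- dim(n_cube)[1]
  if (is.null(geom)) {
    geom <- scatter_geometry(cell_size, scatterer_half = (side - 1) / 2,
                             medium_index = medium_index)
  }
  run <- plane_wave_scatter_run(geom, n_cube, wavenumbers, ...)
  nk <- dim(run$E_sca)[2]
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phv <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  gr <- expand.grid(th = th, ph = phv)
  dirs <- cbind(sin(gr$th) * cos(gr$ph), sin(gr$th) * sin(gr$ph), cos(gr$th))
  wdir <- sin(gr$th) * (pi / n_theta) * (2 * pi / n_phi)
  out <- data.frame(lambda_um = 2 * pi / wavenumbers,
                    sigma_s_um2 = NA_real_, mu_s_mm = NA_real_, g = NA_real_)
  eta <- C_UM_FS / medium_index
  for (k in seq_len(nk)) {
    E_sca <- run$E_sca[, k, ]
    H_sca <- run$H_sca[, k, ]
    S_sca <- poynting(E_sca, H_sca)
    flux <- sum(facet_normal_sum(geom$surface, S_sca))
    sig <- flux / run$I_inc[k]
    k_med <- wavenumbers[k] * medium_index
    pat <- ntff_pattern(geom$surface, E_sca, H_sca, k_med, eta, dirs)
    g <- sum(pat * dirs[, 3] * wdir) / sum(pat * wdir)
    out$sigma_s_um2[k] <- sig
    out$mu_s_mm[k] <- concentration * sig * 1e3
    out$g[k] <- g
  }
  attr(out, "run") <- run
  out
}

#' Optimize a scatterer design against a Mie Poynting target
#'
#' Nelder-Mead minimization of [poynting_mismatch()] over selected octant
#' parameters, with bound enforcement by projection (parameters are clamped
#' into the allowed index range before each evaluation). One PSTD plane-wave
#' run evaluates all target wavelengths at once via the running DFT. The
#' homogeneous reference run is computed once and reused.
#'
#' @param initial A [scatterer_design()].
#' @param target List with `S_mie` (nv x 3 x n_lambda), `weights`,
#'   `wavenumbers` (rad/um).
#' @param geom A [scatter_geometry()] whose surface generated the target.
#' @param free_idx Indices (1..64) of octant parameters to optimize; the
#'   rest stay fixed. Default: all 64.
#' @param max_evals Evaluation budget.
#' @param reltol Relative convergence tolerance on epsilon.
#' @param medium_index Embedding medium index.
#' @param reference Optional precomputed homogeneous reference run (reused
#'   for every evaluation; computed on the first evaluation otherwise).
#' @param ... Passed to [plane_wave_scatter_run()].
#' @return List: `design` (optimized), `eps` (final mismatch), `trace`
#'   (best-so-far mismatch per evaluation, non-increasing), `evals`,
#'   `converged`.
#' @export
optimize_design <- function(initial, target, geom, free_idx = seq_len(64),
                            max_evals = 200, reltol = 1e-4,
                            medium_index = 1.42, reference = NULL, ...) {
  stopifnot(inherits(initial, "scatterer_design"))
  bounds <- initial$bounds
  params <- initial$params
  trace <- numeric(0)
  best <- Inf; best_p <- params
  evals <- 0
  objective <- function(p_free) {
    if (evals >= max_evals) return(best)   # budget exhausted: flat
    p <- params
    p[free_idx] <- pmin(pmax(p_free, bounds[1]), bounds[2])
    cube <- expand_symmetric(p, bounds)
    res <- pstd_scattered_poynting(cube, geom, target$wavenumbers,
                                   reference = reference, ...)
    if (is.null(reference)) reference <<- res$run$reference
    eps <- poynting_mismatch(res$S_tilde, target$S_mie, geom$surface,
                             target$weights)
    evals <<- evals + 1
    if (eps < best) { best <<- eps; best_p <<- p }
    trace <<- c(trace, best)
    eps
  }
  if (length(free_idx) == 1) {
    opt <- stats::optimize(objective, interval = bounds, tol = reltol)
  } else {
    opt <- stats::optim(params[free_idx], objective, method = "Nelder-Mead",
                        control = list(maxit = max_evals, reltol = reltol))
  }
  design <- scatterer_design(best_p, initial$cell_size, bounds)
  list(design = design, eps = best, trace = trace, evals = evals,
       converged = evals < max_evals)
}
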