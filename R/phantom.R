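#' Place scatterers uniformly inside a masked region
#'
#' Draws a Poisson-distributed number of scatterer centers (mean =
#' concentration x region volume), positions them uniformly over the masked
#' cells of the grid lattice, and resolves bounding-cube overlaps by
#' rejection resampling. Deterministic given the seed.
#'
#' @param mask Logical array (grid dims): admissible center cells.
#' @param cell_size Cell size (um).
#' @param concentration Number density (um^-3).
#' @param seed RNG seed.
#' @param stamp_half Half-extent of the scatterer bounding cube in cells
#'   (3 for a 7^3 design); used for the overlap test.
#' @return Integer matrix (n x 3) of center cell indices (1-based).
#' @export
place_scatterers <- function(mask, cell_size, concentration, seed,
                             stamp_half = 3) {
  stopifnot(concentration >= 0)
  d <- dim(mask)
  vol <- sum(mask) * cell_size^3
  if (vol <= 0) stop("region volume must be positive")
  set.seed(seed)
  n_target <- stats::rpois(1, concentration * vol)
  if (n_target == 0) return(matrix(integer(0), 0, 3))
  admissible <- which(mask)
  centers <- matrix(integer(0), 0, 3)
  occupied <- integer(0)
  attempts <- 0L
  failures <- 0L
  min_sep <- 2 * stamp_half + 1
  while (nrow(centers) < n_target) {
    attempts <- attempts + 1L
    cand <- admissible[sample.int(length(admissible), 1)]
    ijk <- arrayInd(cand, d)
    ok <- TRUE
    if (nrow(centers) > 0) {
      sep <- abs(sweep(centers, 2, as.integer(ijk)))
      if (any(apply(sep, 1, max) < min_sep)) ok <- FALSE
    }
    if (ok) {
      centers <- rbind(centers, as.integer(ijk))
    } else {
      failures <- failures + 1L
    }
    if (attempts > 20 && failures > 0.3 * attempts) {
      stop("requested density too high for non-overlapping placement")
    }
  }
  unname(centers)
}

#' Stamp a scatterer design into a refractive-index volume
#'
#' @param n_volume Background refractive-index array (modified copy
#'   returned).
#' @param cube Scatterer index cube (odd side).
#' @param centers Integer matrix (n x 3) of center cells.
#' @param background_index Cells of the cube equal to this value are treated
#'   as transparent (not stamped), so designs only overwrite their
#'   scattering cells.
#' @return The updated array. Stamps extending past the volume edge are
#'   clipped with a warning.
#' @export
stamp_scatterers <- function(n_volume, cube, centers,
                             background_index = 1.42) {
  d <- dim(n_volume)
  side <- dim(cube)[1]
  h <- (side - 1) / 2
  offs <- arrayInd(seq_len(side^3), dim(cube)) - (h + 1)
  vals <- as.vector(cube)
  active <- vals != background_index
  offs <- offs[active, , drop = FALSE]
  vals <- vals[active]
  clipped <- FALSE
  for (r in seq_len(nrow(centers))) {
    p <- sweep(offs, 2, centers[r, ], `+`)
    inside <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    if (!all(inside)) clipped <- TRUE
    pi <- p[inside, , drop = FALSE]
    n_volume[pi] <- vals[inside]
  }
  if (clipped) warning("scatterer stamp clipped at the volume edge")
  n_volume
}

#' Structured (letter) scattering phantom
#'
#' Builds a refractive-index volume: homogeneous background with scatterer
#' designs stamped at random positions whose centers fall inside the letter
#' masks, at the requested concentration.
#'
#' @param grid A [grid_spec()].
#' @param mask Logical array (grid dims) marking the letter volumes; NULL
#'   for an empty (homogeneous) phantom.
#' @param cube Scatterer refractive-index cube (from [expand_symmetric()] or
#'   [design_cube_from_cells()]).
#' @param concentration Number density (um^-3).
#' @param seed RNG seed.
#' @param background_index Embedding medium index.
#' @return List of class `material_map`: `n` (index array), `centers`,
#'   `cell_size`.
#' @export
build_letter_phantom <- function(grid, mask, cube, concentration, seed,
                                 background_index = 1.42) {
  n <- array(background_index, grid$dims)
  if (is.null(mask) || !any(mask) || concentration == 0) {
    return(structure(list(n = n, centers = matrix(integer(0), 0, 3),
                          cell_size = grid$cell_size), class = "material_map"))
  }
  stopifnot(all(dim(mask) == grid$dims))
  h <- (dim(cube)[1] - 1) / 2
  centers <- place_scatterers(mask, grid$cell_size, concentration, seed,
                              stamp_half = h)
  n <- stamp_scatterers(n, cube, centers, background_index)
  structure(list(n = n, centers = centers, cell_size = grid$cell_size),
            class = "material_map")
}

#' Sparse phantom for point-spread-function measurement
#'
#' Full-volume placement at a density low enough that scatterers appear
#' isolated: the default concentration makes the nearest-neighbor distance
#' exceed `isolation_factor` lateral PSF widths with probability
#' `isolation_prob` (Poisson nearest-neighbor statistics).
#'
#' @param grid A [grid_spec()].
#' @param cube Scatterer index cube.
#' @param psf_fwhm_lat Lateral PSF FWHM (um).
#' @param concentration Number density (um^-3); default from the isolation
#'   criterion.
#' @param seed RNG seed.
#' @param background_index Medium index.
#' @param isolation_factor,isolation_prob Isolation criterion parameters.
#' @return A `material_map`.
#' @export
build_psf_phantom <- function(grid, cube, psf_fwhm_lat, concentration = NULL,
                              seed = 1L, background_index = 1.42,
                              isolation_factor = 5, isolation_prob = 0.95) {
  dmin <- isolation_factor * psf_fwhm_lat
  c_iso <- -log(isolation_prob) / ((4 / 3) * pi * dmin^3)
  if (is.null(concentration)) {
    concentration <- c_iso
  } else if (concentration > c_iso) {
    warning(sprintf(
      "density %.3g exceeds the isolation limit %.3g um^-3", concentration,
      c_iso))
  }
  mask <- array(TRUE, grid$dims)
  # keep stamps clear of the boundary
  h <- (dim(cube)[1] - 1) / 2 + 1
  mask[c(seq_len(h), grid$dims[1] - seq_len(h) + 1), , ] <- FALSE
  mask[, c(seq_len(h), grid$dims[2] - seq_len(h) + 1), ] <- FALSE
  mask[, , c(seq_len(h), grid$dims[3] - seq_len(h) + 1)] <- FALSE
  build_letter_phantom(grid, mask, cube, concentration, seed,
                       background_index)
}

#' Low-contrast calibration phantom
#'
#' Identical placement machinery with the scattering cells set to index
#' 1.421 on a 1.42 background: a negligibly scattering phantom used to
#' measure the confocal signal envelope. With the same seed as a paired
#' scattering phantom, the scatterer positions are identical.
#'
#' @param grid A [grid_spec()].
#' @param cube Scatterer cube whose scattering cells define the stamp shape.
#' @param mask Logical array or NULL for full volume.
#' @param concentration Number density (um^-3).
#' @param seed RNG seed.
#' @param background_index Medium index (default 1.42).
#' @param stamp_index Calibration index (default 1.421).
#' @return A `material_map`.
#' @export
build_calibration_phantom <- function(grid, cube, mask, concentration, seed,
                                      background_index = 1.42,
                                      stamp_index = 1.421) {
  calib <- cube
  calib[cube != background_index] <- stamp_index
  if (is.null(mask)) {
    mask <- array(TRUE, grid$dims)
  }
  build_letter_phantom(grid, mask, calib, concentration, seed,
                       background_index)
}

#' Rasterize 2D letter masks into a 3D grid mask
#'
#' Extrudes a binary 2D (x, z) mask uniformly along y. Convenience for
#' B-scan-style structured phantoms.
#'
#' @param mask2d Logical matrix (nx x nz).
#' @param dims Grid dims.
#' @return Logical array.
#' @export
extrude_mask <- function(mask2d, dims) {
  stopifnot(nrow(mask2d) == dims[1], ncol(mask2d) == dims[3])
  aperm(array(rep(mask2d, dims[2]), c(dims[1], dims[3], dims[2])), c(1, 3, 2))
}
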