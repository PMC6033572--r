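---
title: "Full-wave OCT image formation: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-wave OCT image formation: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`octsim` simulates image formation in spectral-domain optical coherence
tomography (OCT) from first principles. One A-scan is one full solution of
Maxwell's equations: a focused, pulsed beam is launched into a refractive
index volume, the scattered light is coupled back into the delivery fiber,
interfered with a reference reflection, corrupted by shot noise, and
transformed into a depth profile. Because the field is propagated exactly
(up to discretization), multiple scattering, dependent scattering, coherence
changes and speckle emerge from the model rather than being imposed.

The pipeline has five stages:

1. **Illumination.** The fiber mode is a unit-energy Gaussian whose 1/e²
   intensity diameter equals the mode field diameter (the weakly-guiding
   approximation). It is collimated by a 4f relay (`f1`, `f2`), truncated by
   the aperture `Ra`, and focused with the Debye–Wolf diffraction integral,
   which keeps the full vectorial structure of the focal field. The default
   system (`optical_system()`) is a 1300 nm spectral-domain scanner:
   `f1 = 25 mm`, `f2 = 36 mm`, `Ra = 3.5 mm`, MFD `9.2 um`, band
   1180–1420 nm, 2048 spectral samples, NA ≈ 0.097.
2. **Propagation.** A pseudospectral time-domain (PSTD) solver advances E
   and H on a collocated uniform cubic grid: spatial derivatives by FFT
   (exact for band-limited fields, so the grid can approach two samples per
   in-medium wavelength), leapfrog in time. The focused field enters through
   a planar magnetic current density
   `J*(t) = Re{-k̂ × e_ill exp(-i w0 (t - t0))} exp(-pi ((t-t0)/W)^2)`.
   `w0 = c k0`; the envelope width `W` is chosen so the source amplitude
   spectrum stays at or above 10% of peak across the configured band
   (`source_envelope_width()`, ≈ 36.5 fs for 1180–1420 nm), and `t0 = 5 W`
   leaves the envelope below 1e-6 of peak at `t = 0`.
3. **Detection.** The coupling of the total field into the fiber is the
   scalar unconjugated overlap of the transverse field with the illumination
   field on the detection plane, evaluated per wavenumber by a running
   discrete Fourier transform as the solver steps (convention `exp(+i w t)`
   throughout). Three couplings enter the interferogram: sample
   (`alpha_tot`), mirror reference (`alpha_ref`) and homogeneous-grid
   illumination (`alpha_ill`); the detected power is
   `i(k) = |alpha_tot - alpha_ill + alpha_ref - alpha_ill|^2` with the
   proportionality constant fixed at 1 (all absolute scale lives in the
   detector's quantum efficiency). The illumination term is subtracted twice
   because the source sheet radiates both up and down the axis.
4. **Noise.** Photon counts `n(k) = eta i(k)` are replaced by Poisson draws.
   `eta` is not a physical constant here but the single free calibration of
   the model: `calibrate_eta()` bisects on `log eta` until a
   region-of-interest SNR matches a target, which mirrors how a simulated
   image is matched to a measured one.
5. **Reconstruction.** `A(z) = (1/2pi) sum S(k) n(k) exp(i 2 k z) dk`, with
   the round-trip factor 2, a Hanning `S(k)` spanning the band, and display
   depths scaled to physical distance by the group index (1.42 for the
   silicone phantom; whether the display scaling should use the phase or
   the group index is ambiguous for this material, and the two coincide
   under the measurement assumption that the group index estimates the
   phase index).

# The discrete-scatterer problem and the optimized design

On a grid with cells of `lambda0/6` (≈ 217 nm) a 1 um sphere is a stair-case
blob a few cells across, and its scattering properties differ badly from the
sphere it stands for. `discretize_sphere()` provides three deliberately
different stair-case constructions (cell centers inside the radius with the
sphere centered on a cell center; the same with the center on a cell corner;
a half-volume-coverage test with the center on a cell face). The third
construction deviates from a plain half-volume test centered on a cell
center because at exactly the 1 um / lambda0-6 combination that test
reproduces construction one cell-for-cell; the face-centered variant keeps
the three shapes mutually distinct, which is the property the comparison
needs.

The remedy is an optimized scatterer: a 7³ cube of refractive indices,
reduced to 4³ free values by mirror symmetry about the three cell planes
bisecting the cube (`expand_symmetric()`), bounded to [1, 3.5], and fitted
so that the time-averaged Poynting flux it sends through a closed cubic
reference surface matches the Mie solution of the target sphere across the
spectrum. The mismatch is the spectrum-weighted, facet-quadrature relative
squared error of the normal flux (`poynting_mismatch()`), and the search is
a projected Nelder–Mead (`optimize_design()`). Matching the spatial
distribution of energy flux on a closed surface across wavelengths matches
the scattering cross-section and asymmetry parameter implicitly.

Two conventions matter and are both used deliberately: the mismatch compares
*total-field* Poynting vectors (analytic incident plus computed scattered,
as the Mie target includes the incident wave), while cross-section
characterization integrates the *scattered-field* Poynting flux through the
same surface and obtains `g` from a Stratton–Chu near-to-far-field
transform of the scattered tangential fields.

# Numerical choices

* **Stability.** The collocated FFT leapfrog is stable for
  `dt <= 2 Delta / (c_max pi sqrt(D))` (`stability_limit()`); production
  defaults use 0.9–0.95 of the bound. At `Delta = lambda0/6` in 3D the bound
  is ≈ 0.266 fs, consistent with the 0.252 fs step the full-scale
  configuration uses. Near the bound the leapfrog's temporal dispersion
  makes group velocities read a few percent fast; pulse-speed validations
  therefore run at ~0.35 of the bound, where the error is below 1%.
* **Absorbing boundary.** An impedance-matched graded-conductivity layer
  (identical multiplicative damping on E and H, polynomial grading of order
  3, 10 cells) absorbs at normal incidence with measured amplitude
  reflection between 3e-3 (coarsest grids) and 5e-6 (finest), well inside
  the -40 dB power target. Two placement rules follow from measurements: the layer must not touch reactive near
  fields, so scattering geometries keep ≈ 0.7 lambda0 of clearance between
  the reference surface and the absorber (`scatter_geometry()` scales this
  clearance in wavelengths, not cells), and grids are padded to 5-smooth
  dimensions because the FFT cost on prime-length axes is several-fold
  higher.
* **Plane-wave runs.** Characterization uses the scattered-field
  formulation: the solver advances the scattered field directly, driven by
  the contrast source `-((eps - eps_bg)/eps) dE_inc/dt` inside the
  scatterer cells, with `E_inc` an analytic x-polarized plane-wave pulse.
  The incident wave never exists on the grid, so it is exactly uniform (a
  sheet-launched beam clipped by the side absorbers loses up to tens of
  percent of uniformity at the reference surface — measured, and the reason
  this formulation is used), the absorber only sees outgoing waves, and no
  homogeneous reference run is needed. Incident spectra and intensity enter
  all normalizations analytically. A contrast-free design scatters exactly
  nothing by construction.
* **Surface placement.** Reference-surface vertices sample the scattered
  near field; within ~0.4 lambda0 of the high-contrast stair-case boundary
  the pointwise-permittivity PSTD field carries cell-scale (Gibbs)
  structure that the facet quadrature does not integrate out, so the
  surface keeps at least that physical standoff from the scatterer
  (margins scale with wavelength, not cell count). At `lambda0/6` the
  vertex lattice samples the scattered wave at only ~4 points per in-medium
  wavelength, which leaves an irreducible ~10% uncertainty on
  cross-sections measured at that cell size (cross-sections at `lambda0/12`
  and finer are stable to ~1%); the mismatch functional compares both sides
  on the same lattice and is unaffected.
* **Ring-down.** High-contrast scatterers store resonant energy; spectra
  accumulated before the interior field has drained are biased. Run lengths
  scale with the domain transit time plus the source duration
  (`run_time_factor`); characterization accuracy was verified to be
  insensitive to further lengthening at the settings used in the tests.
* **Debye–Wolf evaluation.** Direct midpoint quadrature in (theta, phi)
  with aplanatic apodization and Richards–Wolf polarization vectors,
  evaluated as matrix products of complex exponentials. At NA 0.1–0.33 and
  the plane sizes used this is simpler and at least as accurate as an
  FFT/chirp-z evaluation; the untruncated low-NA focus matches the paraxial
  Gaussian closed form to < 0.1% in FWHM.
* **Attenuation fit.** `I = I0 exp(-2 mu_s (z - z0))` on the ratio of a
  high-scattering averaged intensity A-scan to a low-contrast calibration
  average (the confocal function cancels in the ratio). `z0` is pinned to
  the start of the fit range because it is exchangeable with `I0`.
  Uncertainty comes from refitting under Gaussian perturbations of each
  ratio point (default 500 refits) and reporting the SD of the refit
  distribution.
* **PSF extraction.** Candidate voxels are the top 0.05% of the C-scan by
  an order-statistic threshold; 26-connected components give candidate
  centers; 1D Gaussian fits along x and z supply sub-pixel centers and
  FWHMs, and a normalized RMS residual above 0.15 rejects blended
  multi-scatterer blobs. A genuine limitation: two equal scatterers merged
  at half a FWHM are numerically indistinguishable from one slightly wider
  scatterer, so fit quality cannot reject them; they bias PSF statistics.
* **Autocovariance.** Biased FFT estimator on linear-amplitude images,
  averaged over the orthogonal axis, normalized at zero lag, FWHM by linear
  interpolation of the half crossing.

# The speckle surrogate and what it does and does not show

Full B-scans of the structured phantom at experimental scale are a
supercomputer workload (hundreds of CPU-days). For desk-scale statistics the
package provides a PSF-convolution speckle generator
(`simulate_speckle_bscan()`): dense random complex scatterers (circular
Gaussian amplitudes, many per resolution cell) convolved with the separable
system PSF. The axial kernel is the reconstruction transform of the
Hanning-windowed band with depths scaled by the medium index; the lateral
kernel is the **square** of the in-focus Debye–Wolf field, because a
fiber-coupled point scanner both illuminates and detects through the same
mode, making the image-domain lateral response confocal. Using the bare
(unsquared) focal field would overestimate the lateral speckle width by
roughly 40%.

This surrogate reproduces first-order speckle statistics (Rayleigh
amplitudes, fully developed speckle) and second-order widths
(autocovariance FWHM along both axes). It does not capture multiple or
dependent scattering, depth-dependent defocus, attenuation within the
letters, or shadowing — all of which the full PSTD pipeline does capture; a
few-percent disagreement with full-wave values is expected and the
tolerances used in the acceptance checks reflect that.

Default speckle study conditions: 400 x 400 images at 0.5 um axial x 1.0 um
lateral sampling, 2 scatterers per pixel (≈ 10^2 per resolution cell), 10
seeds. These are fixed study conditions, not tuning knobs.

# Desk-scale problem sizes

The test and acceptance suites run every physical claim at reduced scale:
1D grids of a few hundred cells for propagation, absorber and
interferometry checks; 3D grids of 40–90 cells per axis for plane-wave
characterization (cell sizes lambda0/6 to lambda0/24 of the 1 um design
sphere); optimizer demonstrations with 2 free octant parameters and a
surface hugging the scatterer. The full 64-parameter optimization at the
original production scale and full-size B-scans are supported by the same code paths
but take days-to-months of CPU; nothing in the implementation caps the
problem size.

# Known limitations

* Isotropic, non-dispersive, non-magnetic media only; the TiO2 particles'
  uniaxial birefringence and wavelength-dependent index are not modeled
  (their bulk indices at 589 nm are the best available inputs, a documented
  uncertainty of the phantom itself).
* The matched-conductivity absorber is not a true complex-stretched PML:
  evanescent fields that reach it are absorbed rather than returned, hence
  the wavelength-scaled clearance rule above.
* The 4f illumination model is an approximation to the real scan-lens
  prescription; aberrations and chromatic focal shift are out of scope.
* The scalar coupling integral neglects the vectorial subtleties of fiber
  coupling; at NA 0.1 the longitudinal field is ≤ 5% of the transverse
  magnitude.
* The optimized-scatterer inverse problem is non-unique and the solutions
  oscillatory; the optimizer finds *a* design with matched flux, not a
  stable reconstruction.
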