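# octsim

Full-wave simulation of image formation in spectral-domain optical
coherence tomography (OCT), with optimized discrete-scatterer design and
quantitative image analysis.

## The problem

OCT images of scattering media are shaped by wave effects — speckle,
multiple scattering, coherence gating, confocal collection — that simpler
image models (convolution, Monte-Carlo) cannot reproduce for deterministic
refractive-index structures. This package implements an image-formation
model built directly on Maxwell's equations, for people who need
physically faithful synthetic OCT data: a pseudospectral time-domain (PSTD)
solver advances the electromagnetic field through a refractive-index volume;
the illumination is the vectorial Debye–Wolf focus of a Gaussian fiber mode
through a 4f relay; detection is the scalar overlap of the scattered field
with the fiber mode; shot noise is Poisson; and the A-scan is the windowed
spectral transform

    A(z - z_ref) = (1 / 2π) Σ S(k) ñ(k) exp(i 2 k (z - z_ref)) Δk,

with `ñ(k) ~ Poisson(η · i(k))` and
`i(k) ∝ |α_tot - α_ill + α_ref - α_ill|²`.

A second problem the package addresses: on PSTD grids with cells ~λ/6, a
micrometre-scale sphere becomes a crude stair-case of cubes whose scattering
coefficient μ_s and asymmetry parameter g differ badly from Mie theory.
`octsim` implements the remedy — an optimized 7³-cell scatterer, reduced to
4³ free refractive indices by mirror symmetry, fitted by Nelder–Mead so that
its time-averaged Poynting flux through a closed reference surface matches
the Mie solution of the target sphere across the source spectrum:

    ε(n) = Σ_m S(λ_m) · Σ_f |v̂_f·(A_f/3)·Σ_{l∈f}(S̃_l(n,λ_m) - S_l(λ_m))|²
                        / Σ_f |v̂_f·(A_f/3)·Σ_{l∈f} S_l(λ_m)|²

An analytic Lorenz–Mie module (coefficients, cross-sections, asymmetry
parameter, exterior near fields and Poynting vectors) provides the design
targets and the reference physics, and an analysis module implements
speckle autocovariance widths, automatic PSF extraction with Gaussian fits,
Rayleigh amplitude statistics, and confocal-calibrated exponential
attenuation fits with perturbation-based uncertainties.

## Worked example

The structured phantom this model was built around disperses 1 μm TiO₂
spheres (rutile index 2.609) in silicone (index 1.42) at 4.5×10⁻³
particles/μm³. Its design scattering coefficient, and the effective value
over a 1180–1420 nm Hanning spectrum:

```r
library(octsim)
sp <- sphere_spec(diameter = 1, n_particle = 2.609, n_medium = 1.42,
                  concentration = 4.5e-3)
scattering_coefficient(sp, lambda_vac = 1.3)
#> [1] 10.56462
kk <- band_wavenumbers(optical_system(), n_k = 201)
spectrum_weighted_mu_s(sp, kk, hanning_spectrum(kk))
#> [1] 11.48661
mie <- mie_coefficients(sp, 1.3)
asymmetry_parameter(mie)
#> [1] 0.3832246
```

10.6 mm⁻¹ at the design wavelength, 11.5 mm⁻¹ spectrum-weighted, forward
scattering with g ≈ 0.38.

Speckle statistics of a simulated B-scan of that medium (PSF-convolution
surrogate; the axial kernel is the transform of the Hanning band, the
lateral kernel the confocal in-focus Debye–Wolf profile):

```r
st <- speckle_autocovariance_study(n_seeds = 10, seed = 1)
st$axial_fwhm_um
#> [1] 4.401315
st$lateral_fwhm_um
#> [1] 8.31404
```

— the FWHM of the normalized amplitude autocovariance along depth and along
the scan direction, in micrometres.

A full-wave characterization of a stair-case sphere against Mie theory:

```r
cells <- discretize_sphere(1.0, 1.3 / 6, mode = 1)     # 57 cells
cube <- design_cube_from_cells(cells, 2.609, 1.42)
geom <- scatter_geometry(1.3 / 6, scatterer_half = 3)
characterize_scatterer(cube, 2 * pi / 1.3, 1.3 / 6, concentration = 4.5e-3,
                       geom = geom, W = 6, run_time_factor = 1.5)
#>   lambda_um sigma_s_um2  mu_s_mm         g
#> 1       1.3    2.480722 11.16325 0.4037055
```

versus the Mie values σ_s = 2.35 μm², μ_s = 10.6 mm⁻¹, g = 0.383: this
stair-case over-scatters by ~6% with g 5% high at the centre wavelength,
the three stair-case constructions (`mode = 1, 2, 3`) disagree with each
other across the band, and at λ₀/6 the measured cross-section itself is
uncertain at the ±10% level (four surface vertices per in-medium
wavelength). The optimized design (`optimize_design()`) removes this
object-level ambiguity by matching the Poynting flux of the true sphere.

The command-line front end exposes the same functionality
(`inst/cli/octsim.R mie ...`, `design-scatterer`, `analyze`).

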