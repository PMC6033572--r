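Package: octsim
Title: Full-Wave Simulation of Image Formation in Optical Coherence Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full-wave model of image formation in spectral-domain optical
    coherence tomography (OCT). A pseudospectral time-domain (PSTD) Maxwell
    solver with a matched absorbing boundary advances vectorial fields on a
    uniform cubic grid; focused illumination is computed from a Gaussian
    fiber mode through a 4f system via the Debye-Wolf integral; scattered
    light is coupled back into the fiber by a scalar overlap integral,
    shot noise is applied as Poisson photon statistics, and A-scans are
    reconstructed by a windowed discrete Fourier transform. The package also
    provides an analytic Lorenz-Mie reference (cross-sections, asymmetry
    parameter, exterior fields), an optimized discrete-scatterer design
    method that minimizes a Poynting-flux mismatch against the Mie solution
    on a closed reference surface, structured phantom builders, and
    quantitative image analysis (speckle autocovariance, PSF extraction,
    Rayleigh statistics, confocal-calibrated attenuation fitting).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
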