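Package: stenoflow
Title: Desk-Scale Solution-Strategy Study for Post-Stenotic Transitional Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An energy-preserving incompressible flow simulator for an
    idealized constricted (stenosed) 2-D channel, with three large-eddy
    simulation sub-grid closures (static Smagorinsky, Sigma, and dynamic
    Smagorinsky with Lagrangian averaging), together with the turbulence
    statistics used to rank solution strategies for post-stenotic
    high-frequency flow: Reynolds decomposition, high-pass Fourier mode
    filtering, turbulent kinetic energy, Welch power spectral density, and
    Q-criterion vortex identification. Includes a grid-convergence toolkit
    (generalized Richardson extrapolation with non-uniform refinement
    ratios, observed order of convergence, Kolmogorov-scale resolution
    metrics, Reynolds-number and workload accounting) and deterministic
    synthetic generators for carotid-like pulsatile inflow waveforms and
    planted-statistics test signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
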