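Package: activegcn
Title: Velocity Statistics of Active Particles Driven by Gaussian Colored Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates one-dimensional systems of overdamped self-propelled
    particles whose propulsion is an Ornstein-Uhlenbeck (Gaussian colored)
    noise, and evaluates the unified-colored-noise-approximation (UCNA/MUCNA)
    predictions for the position-dependent velocity distribution of such
    systems: conditional velocity covariances, overall velocity variances
    (exact quadrature, hard-sphere, mean-field, small-persistence-time and
    harmonic-chain closed forms), the effective configurational free energy
    in its mean-field form, and long-wavelength density fluctuations.
    Includes trajectory observables (velocity statistics, pair distribution
    function, effective diameter, Fourier density modes) and a reproducible
    simulation pipeline with YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
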