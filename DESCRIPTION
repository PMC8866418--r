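Package: dcswave
Title: Monte Carlo-Wave Simulation of Continuous-Wave and Time-Domain
    Diffuse Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates diffuse correlation spectroscopy (DCS) measurements
    from first principles by coupling a photon-migration Monte Carlo in a
    layered semi-infinite scattering medium with a wave model of the
    detected speckle field. Photon trajectories carry per-layer scattering
    counts and pathlengths; Brownian scatterer motion, source coherence,
    instrument response broadening, arrival-time gating and photon-counting
    shot noise are applied to synthesize intensity and photon-count time
    series for both continuous-wave and time-domain DCS. Includes the
    closed-form reference models (semi-infinite field autocorrelation,
    pathlength distribution, gated correlation with finite coherence, the
    correlator noise model) used to validate the simulator, and replicate
    orchestration for signal-to-noise, contrast-to-noise and depth
    specificity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
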