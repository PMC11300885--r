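Package: ernasim
Title: Modified Kuramoto Model of Evoked Resonant Neural Activity Under
    Deep Brain Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates evoked resonant neural activity (ERNA) recorded in the
    subthalamic nucleus during deep brain stimulation, using a stochastic
    Kuramoto phase-oscillator network whose coupling strength decays through
    depletion of three synaptic vesicle pools (readily-releasable, recycling
    and reserve). Provides Euler-Maruyama simulation of the coupled
    oscillator/vesicle system, Welch spectrogram feature extraction
    (peak-frequency and amplitude time courses), the two-part on/off
    stimulation cost function, a derivative-free generalized pattern-search
    fitter, and the published stimulation paradigms (long on/off schedules,
    frequency and amplitude sweeps, post-stimulation pulse bursting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
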