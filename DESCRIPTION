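Package: stnbeta
Title: Subthalamic Beta-Band LFP Analysis Under Movement, Medication and
    Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing subthalamic nucleus local field potentials
    (LFP) recorded from sensing-enabled deep brain stimulation devices
    together with accelerometer-based finger-tapping kinematics. The package
    covers the full workflow: a ground-truthed synthetic session generator
    (1/f background, bursty beta-band oscillations, movement-locked beta
    desynchronisation, ECG contamination, line noise, clock offsets between
    recording streams), ECG template-subtraction artifact removal, zero-phase
    filtering, Morlet wavelet time-frequency decomposition with sum
    rescaling to a high-frequency reference band, rest and movement power
    spectra, beta peak and band-power extraction, tap detection and
    behavioural metrics, paired sign-flip permutation tests, cluster-based
    permutation tests across frequency, and linear mixed-effects prediction
    of motor performance from beta power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    lmerTest,
    nortest,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
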