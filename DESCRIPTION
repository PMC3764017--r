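Package: nmjquant
Title: Quantal Analysis of Neuromuscular Junction Intracellular Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and characterizes spontaneous miniature endplate
    potentials (MEPPs), giant MEPPs (GMEPPs) and nerve-evoked endplate
    potentials (EPPs) in intracellular voltage recordings from
    neuromuscular junctions. Amplitudes are normalized to a reference
    resting membrane potential of -75 mV and quantal content is estimated
    by the ratio-of-means method. Pooled MEPP amplitude histograms can be
    decomposed into one or two Gaussian components to detect and validate
    fiber subpopulations, and fiber groups are compared with a
    normality- and variance-gated test-selection rule (Shapiro-Wilk, F
    test, Student/Welch t, Mann-Whitney). A stochastic simulator
    generates gap-free traces and stimulus-locked sweep sets with known
    ground truth, parameterized by presets that emulate wild-type and
    SOD1(G93A) mouse diaphragm cohorts, for end-to-end validation of the
    analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
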