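Package: szloop
Title: Closed-Loop Seizure Detection, Optogenetic Entrainment Metrics, and
    Seizure-Duration Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing closed-loop optogenetic stimulation experiments
    in chronic epilepsy models: a seeded synthetic generator of hippocampal
    local field potentials (1/f background, theta oscillation,
    stimulation-phase-locked component, electrographic seizures with ground
    truth), the four per-second interval features of an online electrographic
    seizure detector (coastline, intermittency, spikiness, coherence) with
    sigmoidal bounding and library matching, a simulated closed-loop controller
    with randomized 50 percent stimulation, Hilbert-phase trial-averaged phase
    locking values and periodogram entrainment power ratios with baseline
    subtraction, and the endpoint statistics on seizure-duration distributions
    (Kolmogorov-Smirnov, paired Wilcoxon, normalized-change t tests,
    interseizure-interval and severity comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
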