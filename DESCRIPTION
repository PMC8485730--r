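Package: stimscope
Title: Simulation and Analysis of Miniscope Calcium Imaging During Deep
    Brain Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic single-photon microendoscope (miniscope)
    calcium-imaging movies with full ground truth, including
    stimulation-locked out-of-focus background contamination, locomotor
    velocity traces and deep-brain-stimulation schedules; implements the
    standard preprocessing chain (spatial downsampling, rigid motion
    correction, dF/F, spatial bandpass); compares three neural-signal
    identification methods (seeded ROI averaging, PCA/ICA with
    spatiotemporal de-mixing, and a simplified constrained NMF with a
    ring background model); and provides downstream event statistics:
    calcium event detection, velocity-binned normalized event rates,
    activated-cell counts by stimulation frequency, and Kruskal-Wallis
    with Dunn's post-hoc testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
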