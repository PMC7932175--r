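Package: rovstereo
Title: Stereo-Camera Fish Length Measurement for Mini-ROV Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating fish fork length from paired underwater video
    frames collected with a mini-ROV stereo-camera rig. Implements checkerboard
    calibration by direct linear transformation (DLT), paired-landmark
    triangulation to fork length, red-laser-scaler (RLS) length estimation, the
    associated measurement-error analysis (percent error, Gamma GLM with log
    link and fixed dispersion, minimum measurable length), field-survey
    summaries (eligibility filtering, validation-object accuracy,
    length-frequency histograms, system yield comparison), and a synthetic
    pool-experiment simulator that regenerates the full
    distance x angle-of-incidence x baseline trial design so the whole pipeline
    is testable without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
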