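Package: pednav
Title: Structured-Light Navigation Simulation for Pedicle Punctures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and accuracy analysis for markerless structured-light
    surgical navigation of cervical pedicle punctures. Plans cylindrical
    drill channels on 3D anatomy, simulates partial structured-light surface
    scans of a rigid spine phantom, registers scan to model (landmark rough
    alignment, statistical outlier removal, ICP fine registration), maps the
    preoperative plan into camera space, tracks a drill sleeve by fixed-radius
    RANSAC cylinder fitting, and quantifies puncture accuracy (entry/exit
    offsets, offset angle, Neo breach grading, summary statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
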