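Package: coultertrace
Title: Continuous Long-Term Coulter Counter Volume Timecourses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for continuous, long-term cell-volume timecourses recorded
    on a Coulter counter. Decodes instrument-style pulse files into
    timestamped single-particle volume events, stitches multi-file recordings
    onto one time axis, applies noise-floor and exclusion-bound filters,
    detects and interpolates debris-corrupted files, extracts volume-histogram
    features (modes, bound pairs, subpopulation tracks, colormap matrices),
    and quantifies growth kinetics by moving-window linear regression,
    bilinear change-point detection, and linear-versus-exponential model
    comparison. A seeded simulator generates instrument-style files with
    known ground truth so the full pipeline can be exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
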