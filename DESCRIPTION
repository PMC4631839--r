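Package: batecg
Title: Bat-Algorithm Feature Selection for ECG Myocardial Infarction Detection
Version: 0.1.0
Authors@R: person("GRIET", "Signal Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the standard and improved (per-dimension
    loudness/pulse-rate) bat-algorithm swarm optimizers and applies them as
    wrapper feature selectors for single-lead electrocardiogram beats.
    Includes the full beat pipeline (Savitzky-Golay denoising, R-peak
    detection, RR-based 1/3-2/3 segmentation, resampling to 200 samples), a
    synthetic generator of normal and ST-elevation infarct beats with known
    ground truth, a nearest-neighbour classifier with
    sensitivity/specificity/accuracy reporting, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
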