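Package: holopollen
Title: Synthetic Airflow-Cytometry Pollen Events, Two-Branch Holography +
    Fluorescence Classification, and Season-Aware Monitoring Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale re-creation of an operational automatic pollen
    monitoring stack. Generates synthetic airflow-cytometry events (paired
    greyscale holograms plus a 13-channel induced-fluorescence vector) for
    pollen taxa and water droplets, applies a deterministic morphological
    prefilter, trains a compact two-branch convolutional neural network that
    remains usable when the fluorescence modality is missing (fluorescence
    dropout during training), abstains below a confidence threshold, and
    evaluates the resulting concentration series against emulated manual
    (Hirst-type trap) measurements with Kendall's tau-b, the manual/automatic
    scaling factor, and the off-season noise ratio, swept over confidence
    thresholds with cross-site envelopes. Models export to and load from the
    ONNX interchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
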