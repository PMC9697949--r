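Package: thermospline
Title: B-Spline Compression and Neural-Network Quantification of
    Thermally Modulated Gas-Sensor Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying two volatile analytes (ethanol and
    acetone) from a single thermally modulated metal-oxide-semiconductor
    gas sensor. Each 501-point output-voltage sweep is compressed to eight
    B-spline control-point ordinates by least-squares fitting with greedy
    backward knot elimination, and a small feed-forward network trained by
    BFGS on a sum-of-squares loss maps the feature vectors to log2 analyte
    concentrations. Includes a calibrated synthetic sweep generator
    emulating a voltage-divider readout of a heater-ramped chemiresistor,
    evaluation metrics (MAE, RMSE, R squared) per analyte and data subset,
    and an end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
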