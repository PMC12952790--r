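Package: quantaflux
Title: Quantal and Evoked Calcium Transient Analysis from Fluorescence Time Series
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Headless analysis engine for calcium-imaging time series exported as
    ROI intensity tables. Estimates time-varying baselines with a sliding-window
    percentile method and converts raw fluorescence to dF/F or, for dual-channel
    (indicator/reference) recordings, to ratiometric dR/R; corrects slow
    photobleaching; detects quantal ("mini") and evoked transients with tunable
    threshold, width and inter-peak distance criteria; fits exponential rise and
    decay time constants by Levenberg-Marquardt least squares; partitions events
    across stimulation-frequency blocks and summarizes stimulus trains
    (facilitation index, post-train decay); and provides the paired
    optical-electrophysiology statistics layer (event matching, detection
    fraction, amplitude correlation, pairwise active-zone tests, IQR flagging,
    Kolmogorov-Smirnov comparisons). A seeded synthetic-recording generator with
    ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    readxl,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic.R'
    'paired-stats.R'
    'io.R'
    'detection.R'
    'kinetics.R'
    'protocol.R'
    'normalization.R'
    'config.R'
    'methods-accessors.R'
    'utils.R'
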