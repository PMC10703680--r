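Package: orgephys
Title: Optogenetic Electrophysiology and Calcium Transient Analysis for
    Neural Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for extracellular silicon-probe recordings
    and calcium-imaging traces from fused neural organoids under
    optogenetic stimulation. Implements channel quality control (rejection
    above twice the median standard deviation), 300-3000 Hz zero-phase
    Butterworth filtering, common median referencing, multi-unit spike
    detection with a Donoho (median-based) noise floor, a 5 s.d.
    threshold, a 2 ms refractory rule and a 40 microvolt amplitude gate,
    classification of active and optogenetically responding channels,
    smoothed population event traces, an exact small-sample Wilcoxon
    signed-rank test, and calcium transient metrics (event frequency and
    width-at-5%-height duration) with one-way ANOVA and Tukey group
    comparisons. Includes ground-truthed simulators for probe recordings
    and GCaMP-like fluorescence traces so every stage is testable without
    raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
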