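Package: flyburst
Title: Burst Segmentation, Trace Classification and Estimation Statistics
    for Drosophila Seizure Phenotypes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantifying seizure phenotypes in
    Drosophila. Segments larval motor-neuron spike trains into bursts with an
    inter-spike-interval threshold rule, computes per-trace and per-genotype
    burst statistics, classifies traces as normal or elongated bursting
    against a wild-type reference band (mean +/- k SD), and performs
    estimation statistics for behavioral seizure and locomotion assays:
    bootstrap mean differences with BCa or percentile confidence intervals,
    Cohen's d, percent change, cumulative seizing-incidence curves, and
    cross-assay effect-size regression. Includes a synthetic-data generator
    with exact ground-truth burst labels, a config-driven end-to-end runner
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Electrophysiology, TimeCourse, Software, StatisticalMethod
RoxygenNote: 7.3.3
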