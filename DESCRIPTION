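Package: immunodyn
Title: Dynamic Network and Hypergraph Analysis of Multi-Compartment
    Inflammatory Mediator Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for spatiotemporal analysis of multiplex immunoassay
    (Luminex-type) cytokine, chemokine and growth-factor panels measured
    repeatedly in several tissue compartments (e.g. skin, muscle,
    peripheral blood). Provides a validated SummarizedExperiment-based
    container for long-format mediator tables; a Spearman rank
    cross-correlation census with significance counting; Dynamic Network
    Analysis (DyNA) over consecutive ordinal strata with a degree-based
    network-complexity score; Dynamic Hypergraph (DyHyp) analysis that
    detects per-compartment mediator trends in sliding three-timepoint
    windows and tallies hyperedges by the number of compartments they span;
    one-way and two-way ANOVA screens with Holm-Sidak post hoc adjustment
    and volcano-style two-group comparisons; and a synthetic-data generator
    with planted monotone trends and recorded ground truth for calibration
    and recovery testing. A config-driven pipeline runner orchestrates the
    full analysis deterministically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ImmunoOncology, TimeCourse, Network, Proteomics, Software
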