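Package: eegfc
Title: EEG Band Power and Brain-Network Analysis for Functional
    Constipation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for comparing scalp EEG between
    patients with functional constipation and healthy controls across
    resting, cognitive and defecation-related task blocks. Implements
    relative band power by cortical lobe, functional connectivity as the
    imaginary part of coherency, sparsity-thresholded binary brain
    networks with area-under-curve topological features (global
    efficiency, average local efficiency, average clustering
    coefficient), and age-adjusted ANCOVA group statistics with
    Benjamini-Hochberg false-discovery-rate correction and Cohen's d
    effect sizes. Ships a synthetic-cohort generator (1/f background plus
    band-limited oscillators with region-shared lagged sources) so the
    whole pipeline is testable without access to clinical recordings,
    plus minimal EDF read/write support.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
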