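Package: docnet
Title: Dynamic Directed EEG Network Analysis for Disorders of Consciousness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-related EEG analysis pipeline for probing residual
    consciousness in disorders-of-consciousness cohorts. Implements ERP
    preprocessing (FIR band-pass, mastoid re-referencing, epoching, baseline
    correction, amplitude-based trial rejection), mass-univariate condition
    contrasts with false-discovery-rate control, time-varying multivariate
    autoregressive modelling via a Kalman filter, trial-averaged adaptive
    directed transfer function (ADTF) networks, between-group difference
    networks at snapshot latencies, weighted graph properties (clustering,
    path length, global and local efficiency), and their correlation with
    CRS-R clinical scores. A synthetic-data module generates oddball stimulus
    blocks, ERP-bearing time-varying VAR epochs and cohort tables with
    planted score-network associations so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
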