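Package: lesionkit
Title: Virtual-Lesion Analysis of Whole-Brain Network Models with
    Homeostatic Inhibitory Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates focal virtual lesions on weighted structural
    connectomes with a reduced dynamic mean-field model under feedback
    inhibition control, and predicts compensatory cortical areas by two
    independent measures: structurally similar areas ranked by weighted
    Jaccard similarity, and dynamically similar areas ranked by
    post-lesion inhibitory-weight re-adjustment time and weight change.
    Includes a synthetic modular connectome generator, a
    Balloon-Windkessel haemodynamic forward model, functional
    connectivity contrast statistics with FDR correction, and graph
    metrics of functional networks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
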