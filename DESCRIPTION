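Package: qrgfusion
Title: Hybrid Quantum-Classical Multimodal Fusion for Radiogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for hybrid quantum-classical integration of imaging-derived
    and genomic features in binary diagnostic modelling. Implements QAOA-based
    feature selection over a relevance/redundancy QUBO with an exact statevector
    simulator and brute-force oracle, angle encoding and variational quantum
    circuits emitting Pauli-Z expectation features, classical image and genomic
    (self-attention) encoders, a calibration-penalised hybrid training loss with
    a differentiable expected-calibration-error surrogate, patient-level and
    site-held-out evaluation with the full metric suite (accuracy, precision,
    recall, F1, AUC, ECE, ROC and reliability curves), and a synthetic paired
    radiogenomic cohort generator with planted ground truth for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
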