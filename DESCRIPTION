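Package: microkpnnmt
Title: Knowledge-Primed Multitask Neural Networks for Microbiome-Based
    Phenotype and Metadata Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements MicroKPNN-MT, a multitask knowledge-primed neural
    network that predicts host phenotype (healthy or one of several
    diseases) from species-level microbiome relative-abundance profiles
    while simultaneously predicting missing sample metadata (age class,
    gender, BMI class, body site).  The first hidden layer is a masked
    linear layer whose nodes correspond to named biological entities --
    metabolite production/consumption nodes from a producer/consumer
    metabolic network, genus nodes from the NCBI taxonomy, and community
    nodes from a species co-occurrence network -- so that only
    biologically meaningful species-to-node connections can carry weight.
    Observed metadata are fused into the disease decoder directly;
    missing metadata are replaced by decoder predictions.  Includes the
    sample-count-weighted multitask loss, stratified cross-validation,
    macro-averaged multiclass evaluation metrics, attribution-based
    interpretation (integrated gradients and layer conductance), and a
    synthetic-data generator with planted, recoverable signal for
    testing the whole pipeline without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
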