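Package: orbitlearn
Title: Orbital Learning Simulator for Decentralised Healthcare Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator for orbital learning, an actively
    orchestrated decentralised-learning protocol in which a central node
    groups clients into "orbits" by their assessed impact on the shared
    intelligence, cyclically exchanges the shared layers of a split neural
    network within each orbit, isolates anomalous (noise- or label-tampered)
    clients into singleton orbits, and performs bagging-ensemble inference.
    Includes a synthetic five-class ECG-like waveform generator with an age
    covariate and Non-IID client partitioning, the two impact assessors
    (Spearman rank-order weight similarity against a reference model, and
    autoencoder reconstruction distance scored with dynamic time warping),
    a weighted federated-averaging baseline on identical client data, and
    micro-average AUROC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
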