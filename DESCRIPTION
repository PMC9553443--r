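Package: nergan
Title: Conditional Adversarial Named Entity Recognition for Small Annotated Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Character-level named entity recognition for classical-style
    medical text under small annotated corpora, using a conditional
    generative-adversarial sequence labeller. A multigranularity text
    feature encoder (GRU character encoder, Transformer sentence and
    paragraph encoders, CNN chapter encoder) supplies attention data as
    the generator's main input; an entity-distribution seed vector
    conditions a one-dimensional U-shaped generator with skip
    connections; a convolutional discriminator with differentiated
    conditional inputs drives alternating adversarial training; a
    linear-chain CRF decodes label score sequences into BIO tags.
    Includes a synthetic corpus generator with controllable entity-type
    skew, reading/writing of two-column BIO annotation files, and
    entity-level precision/recall/F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
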