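Package: dielnet
Title: Periodic Gene Detection and Sparse Directed Network Inference for
    Diel Transcriptome Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of short diel (day/night) RNA-seq time courses:
    reads-per-million normalisation and expressed-gene filtering; detection
    of 24-hour periodic genes by Morlet wavelet power with white-noise
    surrogate p-values and a replicate-permutation consensus;
    harmonic-regression peak-time estimation; Pearson co-expression
    networks; and sparse directed gene network inference by penalized
    ARX(p) autoregression with a group SCAD penalty, with per-edge
    confidence from a replicate-resampling ensemble.  A synthetic-data
    module generates diel expression tensors and ground-truth ARX systems
    so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
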