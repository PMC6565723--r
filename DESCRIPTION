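Package: burstsim
Title: Mechanistic Simulation of Single-Cell RNA-Seq Counts from
    Transcriptional Bursting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates single-cell RNA sequencing experiments from first
    principles. True transcript counts are drawn from the stationary
    Beta-Poisson law of the two-state (telegraph) promoter model, with
    per-gene, per-cell kinetic parameters built from low-dimensional
    cell-state coordinates (extrinsic variability factors laid out by
    Brownian motion on a user-supplied tree) and sparse gene-effect
    vectors. Observed read or UMI counts are then produced by explicit
    simulation of mRNA capture, length-biased PCR or linear
    amplification, fragmentation and size selection, sequencing, and
    batch effects. Also provides MCMC estimation of kinetic parameters
    from count matrices, calibration of simulation parameters to a
    target dataset by nearest-statistics search, ground-truth labelling
    of differentially expressed genes, and binomial power calculators
    for rare-population detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Matrix,
    ape,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
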