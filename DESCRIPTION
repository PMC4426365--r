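Package: SubstrainDrift
Title: Genetic Drift and Divergence Analysis for Inbred Mouse Substrains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify and simulate genetic drift among closely
    related inbred mouse substrains from homozygous variant calls.
    Simulates Poisson accumulation of fixed mutations along a dated
    substrain genealogy, computes pairwise fixed-difference distance
    matrices and substrain distribution patterns, estimates per-year and
    per-generation fixation rates, fits small-taxon phylogenies by
    neighbor joining and maximum likelihood under the general
    time-reversible model with a molecular-clock likelihood-ratio test,
    estimates pooled-capture sequencing-error and PCR template-switching
    ("jumping PCR") rates from read-level base counts, and calls large
    deletions from ordered array probe intensities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
biocViews: Genetics, SNP, CopyNumberVariation, Phylogenetics, Sequencing
RoxygenNote: 7.3.3
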