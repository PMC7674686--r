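Package: paralogon
Title: Whole-Genome-Duplication-Aware Reconstruction of Gene-Family
    Evolution from Orthology Groups and Microsynteny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the early evolutionary history of a gene
    superfamily on a species tree annotated with whole-genome duplication
    (WGD) events. Combines bootstrap-supported gene-tree clades with
    microsynteny evidence to classify sequences into orthology groups,
    models the probability that shared gene neighborhoods arise by chance,
    and infers per-branch gene origins, losses and tandem duplications by
    Dollo parsimony on presence and Wagner parsimony on copy number, both
    constrained by ohnolog (paralogon) assignments to the two ancestral
    vertebrate whole-genome duplications. Ships the tumor necrosis factor
    superfamily (TNFSF) survey of ten vertebrates as a worked fixture, and
    a seeded birth-death simulator of gene-family histories, gene orders
    and gene trees for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
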