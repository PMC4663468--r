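Package: famevol
Title: Gene Family Expansion, Selection and Expression Divergence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics toolkit for plant gene families, built
    around the four sucrose-metabolism enzyme families (sucrose synthase,
    sucrose phosphate synthase, sucrose phosphate phosphatase and UDP-glucose
    pyrophosphorylase). Provides a profile-based family census from annotated
    proteomes, classification of gene-expansion mechanisms (tandem arrays,
    segmental/collinear blocks, transposable-element carriage with structural
    LTR/Helitron/CACTA/MULE/hAT detectors, retrogenes), neighbor-joining gene
    trees with gene-tree/species-tree reconciliation and ancestral copy
    counts, pairwise Ka/Ks estimation (NG86 with a YN00-compatible mode) and
    a sitewise codon likelihood-ratio scan for purifying/positive selection,
    paralog expression-divergence testing, and a synthetic-evolution
    simulator that emits standard-format datasets with a machine-readable
    truth log for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
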