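Package: toxreghet
Title: Regulatory Barcodes and Spatial Heterogeneity of Venom Toxin Production
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of the cellular and spatial heterogeneity of
    toxin production in a snake venom gland. Links per-toxin transcription
    factor binding repertoires ("regulatory barcodes", from promoter PWM
    scanning and tree-ensemble regulatory network inference) to single-cell
    co-expression modules, promoter/peptide co-evolution (neighbor-joining
    patristic distances), physical genomic distance, and mass spectrometry
    imaging co-occurrence across the gland. Includes a synthetic-data
    generator that plants a co-evolving toxin gene family, TF motif barcodes,
    population-structured single-cell counts, and gland sections with an
    anterior-posterior gradient, so every stage of the pipeline is testable
    without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    edgeR,
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
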