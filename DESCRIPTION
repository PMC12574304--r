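Package: magnetag
Title: Marker-Anchored Recovery and Validation of Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anchoring a metagenome-assembled genome (MAG) to a
    reference ribosomal marker without cultures: parsing GFA1 assembly
    graphs, flagging unitigs that match a reference rDNA operon, extracting
    a bounded graph neighbourhood around the flagged unitigs, colocating
    candidate genome bins on that neighbourhood, linking a bin to a marker
    taxon by multi-sample coverage correlation, and estimating ribosomal
    operon copy number from the regression slope. Includes MAG quality
    diagnostics (assembly statistics, effective completion, SNV
    allele-frequency spectra, per-ORF coverage distributions), comparative
    functional profiling (CAZyme substrate classification, pathway
    completeness scoring, Kruskal-Wallis and Dunn lifestyle comparison with
    compact letter displays), and synthetic-data generators that plant a
    known target genome, coverage structure, and annotation design so every
    stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
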