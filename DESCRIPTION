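Package: tuatlas
Title: Transcript Boundary Mapping and Promoter Modeling from Bacterial
    TSS-Seq and Term-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical identification of bacterial transcription start
    sites from RppH-treated versus untreated 5'-end sequencing coverage,
    Poisson dynamic-lambda calling of RNA 3' termini from term-seq
    coverage, classification of 3' ends into RNA processing sites versus
    transcription termination sites, assignment of start sites to genes
    and transcription units (5' UTRs, leaderless transcripts, regulated
    and constant promoters), an information-theoretic flexible two-hexamer
    sigma-A promoter model (iterative alignment with gap-surprisal spacer
    penalties), and mapping of termination sites onto predicted intrinsic
    terminators with hairpin and U-tract characterization. Includes
    synthetic-data generators with planted ground truth so that every
    stage of the pipeline can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    MASS,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
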