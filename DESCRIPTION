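Package: cfmarker
Title: Tissue-Specific Methylation Markers for Cell-Free DNA Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for developing and running methylation-based liquid
    biopsy assays that quantify tissue-of-origin contributions to
    circulating cell-free DNA (cfDNA). Discovers short, CpG-dense genomic
    regions that are unmethylated specifically in a target cell type
    (e.g. cardiomyocytes) and highly methylated everywhere else, by
    scanning multi-tissue per-CpG methylome matrices. Processes bisulfite
    amplicon sequencing reads into per-molecule CpG methylation calls,
    counts fully unmethylated molecules, and converts unmethylated
    fractions into genome equivalents per ml plasma. Simulates and scores
    the dual-probe droplet digital PCR (ddPCR) version of the same assay
    with Poisson concentration estimation. Includes assay evaluation
    utilities (signal-to-noise, spike-in linearity, limit of detection,
    control cutoffs, ROC curves) and synthetic-data generators for every
    input format, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
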