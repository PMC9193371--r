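Package: ecoRNA
Title: Regulatory Divergence of Coding and Non-Coding RNAs Between Ecotypes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for comparing coding and non-coding RNA
    regulation between two ecotypes of a plant species. Implements lncRNA
    candidate filtering and positional classification, expression
    specificity (Tau) and threshold-based differential-expression flagging,
    ecotype-specific circRNA calling, cis/trans lncRNA target inference,
    competing-endogenous-RNA (ceRNA) network construction by shared-MRE
    hypergeometric testing with expression-correlation gating, selection
    scans from sliding-window FST and nucleotide-diversity ratios,
    per-context (CG/CHG/CHH) DNA-methylation metagene profiling with
    DMR-expression association, and a synthetic multi-omic data generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
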