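Package: toothprior
Title: Prioritization of Candidate Odontogenic Loci from Multimodal
    Regulatory Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts strong and tissue-specific enhancers from chromatin-state
    segmentations of the developing tooth, links enhancers, GWAS variants and
    validated enhancer elements to genes using basal-plus-extension regulatory
    domains and fixed proximity windows, computes permutation-based gene-set
    enrichment with Benjamini-Hochberg correction and Fisher exact contingency
    statistics, and combines the evidence into a point-based prioritized table
    of candidate odontogenic loci with a full per-gene score decomposition. A
    seeded synthetic-data generator plants known enhancer, variant and module
    structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
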