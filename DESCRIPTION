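Package: telofuseq
Title: Telomere Fusion Amplicon Sequencing Analysis During Telomere-Driven Crisis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize telomere fusions captured by fusion-amplicon
    sequencing in cells passing through telomere-driven crisis. Resolves
    amplicon reads into fusion junction calls against a subtelomere reference
    panel (breakpoints, microhomology, insertions and their local templating,
    per-chromatid deletions), classifies fusions as intra-chromosomal,
    inter-chromosomal or genomic, and computes the downstream comparative
    statistics: fusion frequencies per diploid genome, junction-chemistry
    summaries, chromosome and feature-track enrichment against a uniform
    simulated null, copy-number background subtraction and unique-segment
    detection, structural-variant/fusion proximity, variant-allele-frequency
    clonality, and satellite repeat content from normalized read depth.
    Includes a seeded synthetic-data generator that emulates the assay end to
    end for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
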