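Package: sarpscout
Title: SARP-Guided Screening and Prioritization of Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-mining toolkit for screening actinomycete genomes for
    Streptomyces Antibiotic Regulatory Protein (SARP) driven activation
    candidates. Scans replicons for the degenerate SARP-binding heptamer
    consensus (single sites and tandem heptamer-spacer arrays), derives
    intergenic regions and promoter windows, classifies SARP domain
    architectures from profile hit tables, computes global-alignment
    identity/similarity to a reference SARP, scores cluster similarity
    under strict e-value/identity/coverage thresholds, and gates
    biosynthetic gene clusters through a three-step prioritization
    strategy. Includes a deterministic synthetic-genome simulator with
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
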