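Package: strainmarker
Title: Strain-Private SNP Marker Discovery and qPCR Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers strain-specific single-nucleotide markers from panels
    of near-identical bacterial genome assemblies and evaluates the TaqMan
    qPCR assays built on them. Provides a from-scratch maximal-unique-match
    (MUM) pairwise genome aligner with anchor chaining, banded gap closure
    and one-to-one block filtering; SNP extraction from alignment blocks;
    cross-panel intersection to find target-private SNPs with single-copy
    (flank-uniqueness) filtering; TaqMan primer/probe enumeration with
    nearest-neighbor melting temperatures and in-silico PCR specificity
    screening; and the quantification mathematics of qPCR standard curves
    (slope, amplification efficiency, positivity calls, detection limits,
    replicate statistics, CFU per gram). A synthetic-panel generator with
    planted mutation truth makes the whole pipeline testable without
    external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
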