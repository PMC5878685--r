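Package: nickscan
Title: Detection of Persistent Strand-Specific DNA Nicks from 5' End Count Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps persistent site- and strand-specific single-strand DNA
    breaks (nicks) from sonicated sequencing libraries. Implements
    strand-specific per-position read 5'-end count profiles, an
    overdispersed (negative binomial) count null model with upper-tail
    p-values for single positions and window sums, a multi-scale sliding
    window significance scan, and a nick caller based on the sonication
    signature of a confined break: a single-nucleotide 5'-count spike on
    the nicked strand facing a short zone of preferential mechanical
    breakage on the opposite strand. Includes a sonication/end-blunting
    read simulator with toy fission-yeast mating-type reference builders
    so the whole pipeline is testable by parameter recovery, plus binned
    RPKM and IP/WCE enrichment tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
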