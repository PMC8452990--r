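Package: famsurvey
Title: Genome-Wide Gene Family Surveys with Planted-Truth Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide surveys of plant gene
    families such as the subtilisin-like serine proteases (SBTs):
    profile-based identification of domain-bearing family members in a
    proteome, physicochemical characterization (molecular weight,
    isoelectric point, domain architecture), neighbor-joining phylogeny
    with bootstrap support and subfamily assignment against labeled
    references, collinearity chaining with tandem/segmental duplication
    classification, Nei-Gojobori (1986) Ka/Ks estimation with
    Jukes-Cantor correction, promoter cis-regulatory element censuses
    from IUPAC consensus tables, and tissue-specificity classification
    of FPKM expression matrices. A seeded synthetic-genome generator
    plants family genes, duplicate pairs with controlled synonymous and
    nonsynonymous divergence, promoter elements, and expression
    profiles, so that every stage is verifiable against ground truth at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
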