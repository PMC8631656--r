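Package: ssuscan
Title: Locus-Centric Detection of Promoter Translocations and Shared
    Haplotype Analysis at the SSU1 Sulfite-Efflux Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect and characterise convergent chromosomal
    translocations in the promoter of a focal gene (modelled on the yeast
    sulfite-efflux pump gene SSU1) from annotated genome assemblies.
    Classifies each strain's promoter configuration against a reference
    gene neighbourhood, localises translocation breakpoints to base-pair
    resolution with junction-microhomology delimitation, scores retention
    of transcription-factor binding motifs, quantifies shared haplotype
    blocks between strains with Kimura (1981) three-substitution-type
    distances and a random-gene-window permutation test, and summarises
    sulfite-tolerance drop tests and standard-curve-calibrated qPCR
    relative expression. A seeded synthetic-genome generator with planted
    ground truth makes every stage testable without external assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
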