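Package: homoeolog
Title: Homoeologous Region Comparison for Allopolyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares paired homoeologous genomic regions of allopolyploid
    plants such as white clover (Trifolium repens). Pairs homoeologous genes
    between sub-genomes, computes exon/intron/protein identities and
    VISTA-style sliding-window identity profiles, estimates Ks and Ka under
    the Goldman-Yang (GY94) maximum-likelihood codon model with Nei-Gojobori
    (NG86) counting as an independent check, dates sub-genome divergence with
    a synonymous-substitution molecular clock, detects microsynteny against
    reference gene sets with a synteny-quality statistic, assigns haplotypes
    to sub-genomes from progenitor identity and diagnostic variants, and
    simulates paired homoeologous regions with known ground truth so every
    stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
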