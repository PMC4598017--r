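Package: mhcpopgen
Title: Comparative Population Genetics of Adaptive MHC and Neutral Microsatellite Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for contrasting adaptive immunogenetic structure against
    neutral population structure in wildlife. Implements amplicon-based MHC
    genotyping from pooled 454-style reads (demultiplexing, variant
    tabulation, maximum per-amplicon frequency validation, depth-based
    genotype calling and replicate concordance), population diversity and
    differentiation statistics (heterozygosities, rarefied allelic richness,
    nucleotide diversity, AMOVA-based Phi-ST/F-ST, Jost's D), binary-encoded
    multivariate co-structure analysis (Jaccard distances, principal
    coordinates, between-class analysis, co-inertia with the RV permutation
    test), isolation-by-distance Mantel tests, and desk-scale selection
    statistics (Nei-Gojobori dN/dS with a Z-test, likelihood-ratio tests for
    nested codon models). A seeded synthetic-data generator emulating a
    multi-population amplicon study design makes the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    graphics,
    Biostrings,
    ape,
    vegan,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
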