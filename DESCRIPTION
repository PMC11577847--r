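Package: acromap
Title: Sex-Specific Linkage Maps and Recombination Landscapes for Coral Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Construction of sex-specific genetic linkage maps from full-sib
    families of simultaneously hermaphroditic corals genotyped with biallelic
    SNP arrays. Includes a crossover simulator with known sex-specific Marey
    profiles, marker quality control (informativeness classification,
    Mendelian-error and segregation-distortion filtering), two-point
    recombination fraction and LOD estimation with linkage-group formation and
    marker ordering under the Kosambi mapping function, Marey-map cleaning and
    local-polynomial (LOESS) recombination-rate estimation, per-chromosome and
    genome-wide heterochiasmy summaries, and companion tools for gene-level
    alignment identity outliers and repeat-divergence landscapes
    (Kimura to Jukes-Cantor conversion, windowed repeat content).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
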