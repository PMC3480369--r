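Package: cpphylo
Title: Chloroplast Haplotype Phylogeography: Diversity, Differentiation,
    Networks and Expansion Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for range-wide chloroplast-DNA phylogeography of plant
    populations: collapsing aligned intergenic-spacer sequences into
    haplotypes, Nei haplotype and nucleotide diversity, the Pons & Petit
    HS/HT/GST/NST differentiation framework with the NST-vs-GST permutation
    test, hierarchical analysis of molecular variance (AMOVA) with fixation
    indices, Mantel isolation-by-distance tests, median-joining haplotype
    networks, neutrality tests (Tajima's D, Fu's FS), mismatch-distribution
    analysis under sudden demographic and spatial expansion models, and
    conversion of the expansion parameter tau to absolute time. Includes a
    coalescent simulator for expansion and island/stepping-stone histories,
    and a packaged transcription of a 50-population, 26-haplotype oak
    (Quercus variabilis) survey used as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
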