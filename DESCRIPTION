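Package: ystrdiff
Title: Characterizing Y-STR Loci for Population Differentiation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing individual Y-chromosomal short tandem
    repeat (Y-STR) loci in the evaluation of population differentiation.
    Computes the allele frequency difference (AFD) statistic between
    population pairs and its mean over all pairs (mAFD) per locus, ranks
    loci, builds sliding marker panels, and evaluates panels with
    AMOVA-based pairwise genetic distances (Phi-st on squared repeat-count
    differences), permutation tests, and multidimensional scaling. Includes
    quality-control filtering of haplotype tables (null, intermediate and
    duplicated alleles; DYS389 decomposition) and a seeded Wright-Fisher
    forward simulator of multi-population Y-STR haplotypes under the
    stepwise mutation model, so the whole pipeline is exercisable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
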