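Package: FamPath
Title: Tiered Functional Gene-Family Databases with Homolog Decoys for
    Metagenomic Profiling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds tiered (seed, core, full) curated reference databases for
    pathway-organized protein gene families, attaching homolog-decoy groups
    that absorb reads which would otherwise be falsely assigned to target
    families (the "small database issue"). Profiles metagenomic reads against
    such databases with best-hit, homolog-aware assignment, producing
    functional-gene, pathway-level, and taxonomic profiles together with
    accuracy statistics, Bray-Curtis dissimilarities, and principal
    coordinates ordination. Ships a curated registry of 60 cobalamin
    (vitamin B12) biosynthesis gene (sub)families organized into five
    pathway processes, and a seeded simulator of reference families, decoys,
    and fragmented reads for end-to-end evaluation without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
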