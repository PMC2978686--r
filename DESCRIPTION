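Package: domestiscan
Title: Separating Reference Errors from Laboratory-Domestication Variants
    in Sibling C. elegans Lineages
Version: 0.1.0
Authors@R:
    person("Ada", "Merton", email = "ada.merton@example.org",
           role = c("aut", "cre"))
Description: Post-alignment inference chain for comparing two sibling
    Caenorhabditis elegans lineages (the N2 reference strain and LSJ1)
    that diverged during laboratory domestication. Classifies candidate
    strain differences as reference-genome sequencing errors or true
    polymorphisms by a vote across a panel of independently resequenced
    reference-lineage strains, polarizes polymorphisms with two wild
    outgroup isolates, annotates coding consequences (frameshift,
    stop gain, pseudogene rescue), estimates divergence time from a
    per-generation mutation-rate model, tests chromosomal uniformity of
    variant positions, and simulates the advanced-intercross husbandry
    selection experiment. A synthetic-data generator provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
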