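Package: phf
Title: Phage Host Family Agglomeration for Gut Virome Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing gut viromes through predicted phage host
    families (PHFs). Scores concordance between experimentally linked (Hi-C
    proximity ligation) and computationally predicted phage hosts across
    taxonomic ranks under three matching stringencies; agglomerates viral
    OTU abundance tables to the predicted host family level; and quantifies
    how aggregation changes ecological distance (Bray-Curtis, UniFrac),
    longitudinal community stability, and feature prevalence. Includes a
    synthetic longitudinal cohort generator with ground truth so every
    pipeline stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phyloseq
Config/testthat/edition: 3
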