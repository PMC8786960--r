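Package: dyadshift
Title: Strain Sharing and Transcriptional Shifts in Mother-Infant Gut Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects bacterial strains shared between mothers and their
    infants from SNP-haplotype alignments (Jukes-Cantor distances with
    per-species median normalization) and quantifies per-gene-family
    transcriptional activation and deactivation of the shared strains in the
    infant gut relative to the maternal gut, using the median-normalized
    RNA/DNA ratio ("relative expression") from species-stratified gene-family
    abundance tables. Includes community-level diversity statistics
    (Shannon, Bray-Curtis, PERMANOVA), mixed-model differential abundance of
    metabolic pathways with FDR control, and a synthetic mother-infant cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    vegan,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
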