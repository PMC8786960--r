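#!/usr/bin/env Rscript
# Stage 1: simulate a ten-dyad cohort with planted ground truth.
# Writes all five input kinds plus truth.tsv under results/cohort/.
suppressPackageStartupMessages(library(dyadshift))

cfg <- cohort_config(seed = 20260901)
co <- generate_cohort(cfg, out_dir = "results/cohort")

cat("Simulated", cfg$n_families, "mother-infant dyads,",
    cfg$n_species, "species,", cfg$n_genes_per_species,
    "gene families/species.\n")
cat("Planted:", nrow(co$truth$transmissions), "strain transmissions,",
    nrow(co$truth$shifts), "gene-family expression shifts,",
    nrow(co$truth$pathways), "differential pathways.\n")
cat("Inputs and truth.tsv written to results/cohort/\n")
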