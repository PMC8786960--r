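#!/usr/bin/env Rscript
# Stage 5: mother-vs-infant differential abundance of pathways on DNA and
# RNA — prevalence filter (>= 2 samples), mixed model per pathway
# (log10 abundance ~ role + (1 | family)), BH FDR at q < 0.05.
suppressPackageStartupMessages(library(dyadshift))

meta <- read_metadata("results/cohort/metadata.tsv")
for (mol in c("dna", "rna")) {
  tab <- read_pathway_table(
    sprintf("results/cohort/pathways_%s.tsv", mol), toupper(mol))
  res <- test_pathways(prevalence_filter(tab, min_samples = 2), meta)
  out <- sprintf("results/pathway_tests_%s.tsv", mol)
  write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d of %d pathways differential at q < 0.05 (%d higher in infants)\n",
              toupper(mol), sum(res$significant), nrow(res),
              sum(res$significant & res$direction == "higher_in_infants")))
}

truth <- read.delim("results/cohort/truth.tsv")
planted <- truth$pathway_id[truth$kind == "pathway"]
res_dna <- read.delim("results/pathway_tests_dna.tsv")
called <- res_dna$pathway_id[res_dna$significant]
cat(sprintf("DNA recovery vs planted truth: %d/%d planted pathways detected, %d false positives\n",
            sum(planted %in% called), length(planted),
            sum(!called %in% planted)))
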