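#!/usr/bin/env Rscript
# Stage 6: aggregate the published ten-dyad per-species sharing table and
# cohort event counts (shipped under inst/extdata) with the package's
# summarizers — the desk-scale worked example of the sharing summary.
suppressPackageStartupMessages(library(dyadshift))

tab <- read_sharing_counts(
  system.file("extdata", "dyad_sharing_events_table.tsv",
              package = "dyadshift"))
summ <- summarize_sharing(expand_sharing_counts(tab))
write.table(summ$table, "results/published_sharing_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

genus <- genus_of(summ$table$species)
cat(sprintf("Published cohort: %d shared strains, %d species, %d genera\n",
            summ$totals$n_strains, summ$totals$n_species,
            summ$totals$n_genera))
cat(sprintf("Bacteroides: %d events (%.1f%%); Bifidobacterium: %d (%.1f%%)\n",
            sum(summ$table$total[genus == "Bacteroides"]),
            100 * sum(summ$table$total[genus == "Bacteroides"]) /
              summ$totals$n_strains,
            sum(summ$table$total[genus == "Bifidobacterium"]),
            100 * sum(summ$table$total[genus == "Bifidobacterium"]) /
              summ$totals$n_strains))

counts <- read.delim(
  system.file("extdata", "dyad_cohort_counts.tsv", package = "dyadshift"),
  comment.char = "#")
val <- function(q) counts$value[counts$quantity == q]
cat(sprintf("Activation events: %.1f%% of the %d-gene-family universe; deactivation: %.1f%%\n",
            100 * val("activation_events") / val("gene_family_universe"),
            val("gene_family_universe"),
            100 * val("deactivation_events") / val("gene_family_universe")))
cat(sprintf("Unannotated: %.1f%% of activated, %.1f%% of deactivated, %.1f%% overall\n",
            100 * val("activated_unannotated") / val("activated_gene_families"),
            100 * val("deactivated_unannotated") / val("deactivated_gene_families"),
            100 * val("all_unannotated") / val("gene_family_universe")))
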