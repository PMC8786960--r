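#!/usr/bin/env Rscript
# Stage 2: community-level contrast of mothers vs infants —
# Shannon diversity per sample, Bray-Curtis dissimilarities, PERMANOVA on
# role, and the two-sample t-test on diversity.
suppressPackageStartupMessages(library(dyadshift))

meta <- read_metadata("results/cohort/metadata.tsv")
tax <- read_taxonomic_profile("results/cohort/taxonomic_profile.tsv")

div <- data.frame(sample_id = rownames(tax),
                  shannon = apply(tax, 1, shannon_diversity))
div$role <- meta$role[match(div$sample_id, meta$sample_id)]
write.table(div, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

bc <- bray_curtis(tax)
write.table(data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
            "results/bray_curtis.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

perm <- permanova(bc, div$role, n_permutations = 999, seed = 42)
tt <- compare_diversity(div$shannon[div$role == "mother"],
                        div$shannon[div$role == "infant"])
jsonlite::write_json(list(permanova = perm, diversity_t_test = tt),
                     "results/community_tests.json", auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("PERMANOVA on role: R2 = %.3f, p = %.3g\n", perm$R2, perm$p))
cat(sprintf("Mean Shannon diversity: mothers %.2f, infants %.2f (t-test p = %.2g)\n",
            mean(div$shannon[div$role == "mother"]),
            mean(div$shannon[div$role == "infant"]), tt$p))
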