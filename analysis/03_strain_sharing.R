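#!/usr/bin/env Rscript
# Stage 3: strain sharing within dyads — pairwise Jukes-Cantor haplotype
# distances, per-species median normalization, shared-strain calls at
# normalized distance <= 0.2, per-species summary and NJ trees.
suppressPackageStartupMessages(library(dyadshift))

meta <- read_metadata("results/cohort/metadata.tsv")
aln_files <- list.files("results/cohort/alignments", pattern = "\\.fasta$",
                        full.names = TRUE)
alignments <- lapply(aln_files, function(f)
  read_alignment(f, sub("\\.fasta$", "", basename(f))))

dists <- do.call(rbind, lapply(alignments, pair_distances))
dists <- normalize_distances(classify_pairs(dists, meta))
write.table(dists, "results/pair_distances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

events <- call_shared_strains(dists, meta, threshold = 0.2)
write.table(events, "results/sharing_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
summ <- summarize_sharing(events)
write.table(summ$table, "results/sharing_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

dir.create("results/trees", showWarnings = FALSE)
for (sp in unique(events$species)) {
  sub <- dists[dists$species == sp, ]
  ids <- sort(unique(c(sub$sample_a, sub$sample_b)))
  if (length(ids) < 3) next
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(match(sub$sample_a, ids), match(sub$sample_b, ids))] <-
    sub$jc_distance
  writeLines(build_nj_tree(m + t(m)),
             file.path("results/trees", paste0(sp, ".nwk")))
}

wf <- dists$pair_class == "within_family_mother_infant"
cat(sprintf("Mean normalized distance: dyad pairs %.3f, other pairs %.3f\n",
            mean(dists$normalized_distance[wf]),
            mean(dists$normalized_distance[!wf])))
cat(sprintf("Shared strains: %d events, %d species, %d genera\n",
            summ$totals$n_strains, summ$totals$n_species,
            summ$totals$n_genera))

truth <- read.delim("results/cohort/truth.tsv")
planted <- truth[truth$kind == "transmission", ]
hit <- paste(events$species, events$family_id) %in%
  paste(planted$species, planted$family_id)
cat(sprintf("Recovery vs planted truth: %d/%d called events planted, %d planted total\n",
            sum(hit), nrow(events), nrow(planted)))
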