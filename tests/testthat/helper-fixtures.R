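# small in-code fixtures shared across test files

make_metadata <- function(n_families = 3, breastfeeding = NULL) {
  fam <- sprintf("F%02d", seq_len(n_families))
  data.frame(
    sample_id = c(sprintf("M%02d", seq_len(n_families)),
                  sprintf("I%02d", seq_len(n_families))),
    family_id = rep(fam, 2),
    role = rep(c("mother", "infant"), each = n_families),
    breastfeeding = if (is.null(breastfeeding)) "unknown"
                    else rep(breastfeeding, 2),
    site = "NZ", stringsAsFactors = FALSE)
}

# long-format gene-family table from parallel vectors
make_gft <- function(sample_id, species, gene_family, cpm,
                     molecule = "DNA") {
  gene_family_table(
    data.frame(sample_id = sample_id, species = species,
               gene_family = gene_family, cpm = cpm,
               stringsAsFactors = FALSE),
    molecule)
}

# minimal relative-expression records for call_shifts()
make_records <- function(genes, rel, species = "sp", sample = "S1") {
  data.frame(species = species, sample_id = sample, gene_family = genes,
             relative_expression = rel, stringsAsFactors = FALSE)
}

# tiny cohort config for fast tests; any default can be overridden
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_families = 3, n_species = 3, n_genes_per_species = 30,
         alignment_length = 400, n_pathways = 20,
         transmission_probability = 0.5),
    list(...))
  do.call(cohort_config, args)
}
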