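#' Configuration for a synthetic mother-infant cohort
#'
#' Bundles and validates the generator parameters. Defaults describe a
#' ten-dyad pilot-scale cohort: 20 species, 500 gene families per species,
#' haplotypes of transmitted strains nearly identical
#' (1e-4 substitutions/site from the family strain) against a species
#' background of 1e-2, planted activation/deactivation on 10% of the gene
#' families of each transmitted strain at an eight-fold RNA shift, lognormal
#' RNA/DNA noise of sd 0.1, half of gene families unannotated, and 15% of
#' pathways with a four-fold role effect.
#'
#' @param n_families number of mother-infant dyads.
#' @param n_species number of bacterial species.
#' @param n_genes_per_species gene families per species.
#' @param transmission_probability probability that a (family, species) pair
#'   shares a strain.
#' @param transmitted_strain_divergence,background_strain_divergence
#'   substitutions/site between transmitted strains and the family strain,
#'   and between any strain and the species ancestor.
#' @param alignment_length haplotype alignment columns.
#' @param gap_rate per-site probability of an alignment gap in each
#'   haplotype (exercises gap handling; default 0).
#' @param activated_fraction,deactivated_fraction fractions of a transmitted
#'   strain's gene families with planted activation/deactivation.
#' @param activation_fold multiplicative RNA shift of planted events
#'   (must exceed 2 for recoverable truth).
#' @param ratio_noise_sd lognormal sd of the RNA/DNA ratio noise.
#' @param unannotated_fraction fraction of gene families flagged
#'   unannotated (ids carry the `_unknown` suffix).
#' @param n_pathways number of pathways.
#' @param differential_pathway_fraction fraction of pathways with a planted
#'   role effect.
#' @param pathway_effect_size fold change of planted differential pathways.
#' @param pathway_noise_sd lognormal noise sd of pathway abundances.
#' @param seed integer seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 10, n_species = 20,
                          n_genes_per_species = 500,
                          transmission_probability = 0.25,
                          transmitted_strain_divergence = 1e-4,
                          background_strain_divergence = 1e-2,
                          alignment_length = 1000, gap_rate = 0,
                          activated_fraction = 0.1,
                          deactivated_fraction = 0.1,
                          activation_fold = 8, ratio_noise_sd = 0.1,
                          unannotated_fraction = 0.5,
                          n_pathways = 120,
                          differential_pathway_fraction = 0.15,
                          pathway_effect_size = 4, pathway_noise_sd = 0.2,
                          seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(transmission_probability, activated_fraction,
             deactivated_fraction, unannotated_fraction, gap_rate,
             differential_pathway_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (activated_fraction + deactivated_fraction > 1)
    stop("activated_fraction + deactivated_fraction must be <= 1",
         call. = FALSE)
  if (activation_fold <= 2)
    stop("activation_fold must exceed 2 for recoverable ground truth",
         call. = FALSE)
  divs <- c(transmitted_strain_divergence, background_strain_divergence)
  if (any(divs < 0 | divs >= 0.75))
    stop("divergences must lie in [0, 0.75)", call. = FALSE)
  if (ratio_noise_sd < 0 || pathway_noise_sd < 0)
    stop("noise sd must be nonnegative", call. = FALSE)
  if (n_families < 1 || n_species < 1 || n_genes_per_species < 1)
    stop("cohort dimensions must be positive", call. = FALSE)
  if (pathway_effect_size <= 0) stop("pathway_effect_size must be > 0",
                                     call. = FALSE)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "cohort_config"
  cfg
}

#' Mutate a haplotype at a given divergence
#'
#' Each site is independently substituted with probability `divergence`,
#' to a uniformly chosen different base. Uses the current RNG state.
#'
#' @param ancestor sequence over `{A,C,G,T}` (single string).
#' @param divergence substitution probability per site, in `[0, 0.75)`.
#' @return the mutated sequence.
#' @export
mutate_haplotype <- function(ancestor, divergence) {
  if (divergence < 0 || divergence >= 0.75)
    stop("divergence must lie in [0, 0.75)", call. = FALSE)
  chars <- strsplit(ancestor, "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "T")))
    stop("ancestor must be over {A,C,G,T}", call. = FALSE)
  hit <- which(stats::runif(length(chars)) < divergence)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit)
      chars[i] <- sample(setdiff(bases, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Generate a synthetic mother-infant cohort with planted ground truth
#'
#' Emits every input kind the workflow consumes, with known truth:
#' metadata for `n_families` dyads; Dirichlet taxonomic profiles (infants
#' drawn at lower diversity); per-species haplotype alignments in which
#' transmitted (family, species) pairs descend from a common family strain
#' at `transmitted_strain_divergence` while all other strains diverge
#' independently from the species ancestor at
#' `background_strain_divergence`; DNA and RNA gene-family tables where
#' each gene's RNA equals its DNA times lognormal noise, except planted
#' shifts which additionally multiply (activation) or divide (deactivation)
#' the infant RNA by `activation_fold`; and pathway tables with planted
#' role effects of `pathway_effect_size`.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; when given, all inputs plus
#'   `truth.tsv` are written there.
#' @return list with `metadata`, `taxonomic`, `alignments` (per species),
#'   `dna`, `rna`, `pathways_dna`, `pathways_rna`, `truth`
#'   (`transmissions`, `shifts`, `pathways`) and `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  nf <- config$n_families
  families <- sprintf("F%02d", seq_len(nf))
  mothers <- sprintf("M%02d", seq_len(nf))
  infants <- sprintf("I%02d", seq_len(nf))
  metadata <- data.frame(
    sample_id = c(mothers, infants),
    family_id = c(families, families),
    role = rep(c("mother", "infant"), each = nf),
    breastfeeding = c(rep("unknown", nf),
                      sample(c("exclusive", "partial", "none"), nf,
                             replace = TRUE, prob = c(0.4, 0.4, 0.2))),
    site = rep(rep_len(c("NZ", "UK"), nf), 2),
    stringsAsFactors = FALSE)

  species <- sprintf("Species_%02d", seq_len(config$n_species))

  # taxonomic profiles: mothers at higher effective diversity than infants
  tax <- rbind(.rdirichlet(nf, rep(1, config$n_species)),
               .rdirichlet(nf, rep(0.3, config$n_species)))
  rownames(tax) <- metadata$sample_id
  colnames(tax) <- species

  # planted transmissions
  trans <- expand.grid(family_id = families, species = species,
                       stringsAsFactors = FALSE)
  trans <- trans[stats::runif(nrow(trans)) <
                   config$transmission_probability, , drop = FALSE]
  rownames(trans) <- NULL

  # haplotype alignments
  bases <- c("A", "C", "G", "T")
  alignments <- list()
  for (sp in species) {
    ancestor <- paste(sample(bases, config$alignment_length,
                             replace = TRUE), collapse = "")
    seqs <- character(2 * nf)
    names(seqs) <- metadata$sample_id
    transmitted <- trans$family_id[trans$species == sp]
    for (k in seq_len(nf)) {
      if (families[k] %in% transmitted) {
        fam_strain <- mutate_haplotype(
          ancestor, config$background_strain_divergence)
        seqs[mothers[k]] <- mutate_haplotype(
          fam_strain, config$transmitted_strain_divergence)
        seqs[infants[k]] <- mutate_haplotype(
          fam_strain, config$transmitted_strain_divergence)
      } else {
        seqs[mothers[k]] <- mutate_haplotype(
          ancestor, config$background_strain_divergence)
        seqs[infants[k]] <- mutate_haplotype(
          ancestor, config$background_strain_divergence)
      }
    }
    if (config$gap_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        ch <- strsplit(s, "")[[1]]
        ch[stats::runif(length(ch)) < config$gap_rate] <- "-"
        paste(ch, collapse = "")
      }, "")
    }
    alignments[[sp]] <- haplotype_alignment(sp, seqs)
  }

  # gene families: ids carry the annotation flag (suffix _unknown)
  ng <- config$n_genes_per_species
  genes <- lapply(species, function(sp) {
    ids <- sprintf("UF_%s_g%04d", sp, seq_len(ng))
    n_un <- round(config$unannotated_fraction * ng)
    unann <- sample(ng, n_un)
    ids[unann] <- paste0(ids[unann], "_unknown")
    ids
  })
  names(genes) <- species

  # planted shifts on transmitted strains
  n_act <- round(config$activated_fraction * ng)
  n_deact <- round(config$deactivated_fraction * ng)
  shifts <- lapply(seq_len(nrow(trans)), function(i) {
    if (n_act + n_deact == 0) return(NULL)
    ids <- genes[[trans$species[i]]]
    pick <- sample(ng, n_act + n_deact)
    data.frame(family_id = trans$family_id[i], species = trans$species[i],
               gene_family = ids[pick],
               direction = rep(c("activated", "deactivated"),
                               c(n_act, n_deact)),
               stringsAsFactors = FALSE)
  })
  shifts <- shifts[!vapply(shifts, is.null, TRUE)]
  shifts <- if (length(shifts)) do.call(rbind, shifts) else
    data.frame(family_id = character(), species = character(),
               gene_family = character(), direction = character())

  # DNA abundances, then RNA = DNA * lognormal noise (+ planted shifts)
  n_entries <- 2 * nf * config$n_species * ng
  entries <- data.frame(
    sample_id = rep(metadata$sample_id, each = config$n_species * ng),
    species = rep(rep(species, each = ng), times = 2 * nf),
    gene_family = rep(unlist(genes, use.names = FALSE), times = 2 * nf),
    stringsAsFactors = FALSE)
  dna_raw <- stats::rlnorm(n_entries, meanlog = 0, sdlog = 1)
  ratio <- stats::rlnorm(n_entries, meanlog = 0,
                         sdlog = config$ratio_noise_sd)
  rna_raw <- dna_raw * ratio
  if (nrow(shifts)) {
    infant_of <- setNames(infants, families)
    key <- paste(entries$sample_id, entries$species, entries$gene_family)
    act_key <- paste(infant_of[shifts$family_id], shifts$species,
                     shifts$gene_family)
    idx <- match(act_key, key)
    fold <- ifelse(shifts$direction == "activated",
                   config$activation_fold, 1 / config$activation_fold)
    rna_raw[idx] <- rna_raw[idx] * fold
  }
  scale_by_sample <- function(x) {
    tot <- tapply(x, entries$sample_id, sum)
    x * 0.9e6 / tot[entries$sample_id]
  }
  entries_dna <- cbind(entries, cpm = scale_by_sample(dna_raw))
  entries_rna <- cbind(entries, cpm = scale_by_sample(rna_raw))
  dna <- gene_family_table(entries_dna, "DNA")
  rna <- gene_family_table(entries_rna, "RNA")

  # pathways with planted role effects
  pathway_ids <- sprintf("PWY-%04d", seq_len(config$n_pathways))
  n_diff <- round(config$differential_pathway_fraction * config$n_pathways)
  diff_idx <- sample(config$n_pathways, n_diff)
  pw_truth <- data.frame(
    pathway_id = pathway_ids[diff_idx],
    direction = sample(c("higher_in_infants", "higher_in_mothers"),
                       n_diff, replace = TRUE),
    stringsAsFactors = FALSE)
  make_pathways <- function(molecule) {
    base <- stats::rlnorm(config$n_pathways, meanlog = log(50), sdlog = 1)
    mat <- matrix(stats::rlnorm(2 * nf * config$n_pathways, 0,
                                config$pathway_noise_sd),
                  nrow = 2 * nf) * rep(base, each = 2 * nf)
    rownames(mat) <- metadata$sample_id
    colnames(mat) <- pathway_ids
    is_infant <- metadata$role == "infant"
    for (i in seq_len(nrow(pw_truth))) {
      pw <- pw_truth$pathway_id[i]
      if (pw_truth$direction[i] == "higher_in_infants")
        mat[is_infant, pw] <- mat[is_infant, pw] * config$pathway_effect_size
      else
        mat[!is_infant, pw] <- mat[!is_infant, pw] * config$pathway_effect_size
    }
    attr(mat, "molecule") <- molecule
    mat
  }
  pathways_dna <- make_pathways("DNA")
  pathways_rna <- make_pathways("RNA")

  cohort <- list(metadata = metadata, taxonomic = tax,
                 alignments = alignments, dna = dna, rna = rna,
                 pathways_dna = pathways_dna, pathways_rna = pathways_rna,
                 truth = list(transmissions = trans, shifts = shifts,
                              pathways = pw_truth),
                 config = config)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @rdname generate_cohort
#' @param cohort a cohort list from [generate_cohort()].
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
  write_metadata(cohort$metadata, file.path(out_dir, "metadata.tsv"))
  write_taxonomic_profile(cohort$taxonomic,
                          file.path(out_dir, "taxonomic_profile.tsv"))
  for (sp in names(cohort$alignments))
    write_alignment(cohort$alignments[[sp]],
                    file.path(out_dir, "alignments", paste0(sp, ".fasta")))
  write_stratified_table(cohort$dna,
                         file.path(out_dir, "gene_families_dna.tsv"))
  write_stratified_table(cohort$rna,
                         file.path(out_dir, "gene_families_rna.tsv"))
  write_pathway_table(cohort$pathways_dna,
                      file.path(out_dir, "pathways_dna.tsv"))
  write_pathway_table(cohort$pathways_rna,
                      file.path(out_dir, "pathways_rna.tsv"))
  truth <- rbind(
    data.frame(kind = "transmission",
               family_id = cohort$truth$transmissions$family_id,
               species = cohort$truth$transmissions$species,
               gene_family = NA_character_, pathway_id = NA_character_,
               direction = NA_character_, stringsAsFactors = FALSE),
    data.frame(kind = "shift",
               family_id = cohort$truth$shifts$family_id,
               species = cohort$truth$shifts$species,
               gene_family = cohort$truth$shifts$gene_family,
               pathway_id = NA_character_,
               direction = cohort$truth$shifts$direction,
               stringsAsFactors = FALSE),
    data.frame(kind = "pathway", family_id = NA_character_,
               species = NA_character_, gene_family = NA_character_,
               pathway_id = cohort$truth$pathways$pathway_id,
               direction = cohort$truth$pathways$direction,
               stringsAsFactors = FALSE))
  .write_tsv(truth, file.path(out_dir, "truth.tsv"))
  invisible(out_dir)
}
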