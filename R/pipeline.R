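#' Pipeline run configuration
#'
#' Validates the settings for a full workflow run: either a directory of
#' input tables (as laid out by [write_cohort()]) or a simulate block
#' (a [cohort_config()]), the call thresholds, and the output directory.
#'
#' @param out_dir directory for all stage outputs.
#' @param input_dir directory holding `metadata.tsv`,
#'   `taxonomic_profile.tsv`, `alignments/*.fasta`,
#'   `gene_families_{dna,rna}.tsv` and `pathways_{dna,rna}.tsv`.
#' @param simulate a [cohort_config()]; its seed is re-derived from `seed`
#'   so a single pipeline seed controls the whole run.
#' @param sharing_threshold normalized-distance threshold for shared
#'   strains.
#' @param activation_threshold,deactivation_threshold relative-expression
#'   call thresholds; activation must exceed 1, deactivation lie below 1.
#' @param min_overlap minimum compared haplotype sites per pair.
#' @param min_genes minimum gene families per (species, sample) stratum.
#' @param min_samples prevalence filter for pathway testing.
#' @param n_permutations PERMANOVA permutations.
#' @param seed global seed; per-stage seeds are derived by fixed offsets.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(out_dir, input_dir = NULL, simulate = NULL,
                       sharing_threshold = 0.2,
                       activation_threshold = 2,
                       deactivation_threshold = 0.5,
                       min_overlap = 100, min_genes = 10, min_samples = 2,
                       n_permutations = 999, seed = 1) {
  if (is.null(input_dir) && is.null(simulate))
    stop("either input_dir or a simulate block is required", call. = FALSE)
  if (sharing_threshold <= 0 || min_overlap <= 0 || min_genes <= 0 ||
      min_samples <= 0)
    stop("thresholds must be positive", call. = FALSE)
  if (!(activation_threshold > 1 && deactivation_threshold < 1 &&
        deactivation_threshold > 0))
    stop("need activation_threshold > 1 > deactivation_threshold > 0",
         call. = FALSE)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

.stage_seed <- function(config, stage) {
  config$seed + c(simulate = 100L, community = 200L, pathways = 300L)[[stage]]
}

#' Run the full dyad workflow
#'
#' Executes simulate (optional) -> community -> strain sharing ->
#' expression shifts -> pathway differential abundance, writing every stage
#' table under `out_dir` plus a machine-readable `summary.json` and a
#' `run.log`. All randomness derives from the configuration seed.
#'
#' @param config a [run_config()].
#' @return the run summary (also written to `summary.json`), invisibly
#'   containing shared-strain totals, eligible transcribed strains,
#'   activation/deactivation totals and percentages, replication rates and
#'   significant-pathway counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      log_line("stage ", name, " FAILED: ", conditionMessage(e))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- .stage_seed(config, "simulate")
      generate_cohort(sim, out_dir = file.path(config$out_dir, "inputs"))
    } else {
      d <- config$input_dir
      aln_files <- list.files(file.path(d, "alignments"),
                              pattern = "\\.fasta$", full.names = TRUE)
      alignments <- lapply(aln_files, function(f)
        read_alignment(f, sub("\\.fasta$", "", basename(f))))
      names(alignments) <- vapply(alignments, `[[`, "", "species")
      list(metadata = read_metadata(file.path(d, "metadata.tsv")),
           taxonomic = read_taxonomic_profile(
             file.path(d, "taxonomic_profile.tsv")),
           alignments = alignments,
           dna = read_stratified_table(
             file.path(d, "gene_families_dna.tsv"), "DNA"),
           rna = read_stratified_table(
             file.path(d, "gene_families_rna.tsv"), "RNA"),
           pathways_dna = read_pathway_table(
             file.path(d, "pathways_dna.tsv"), "DNA"),
           pathways_rna = read_pathway_table(
             file.path(d, "pathways_rna.tsv"), "RNA"))
    }
  })
  meta <- inputs$metadata

  community <- stage("community", {
    div <- apply(inputs$taxonomic, 1, shannon_diversity)
    diversity <- data.frame(sample_id = rownames(inputs$taxonomic),
                            shannon = div,
                            role = meta$role[match(rownames(inputs$taxonomic),
                                                   meta$sample_id)])
    .write_tsv(diversity, file.path(config$out_dir, "diversity.tsv"))
    bc <- bray_curtis(inputs$taxonomic)
    .write_tsv(data.frame(sample_id = rownames(bc), bc,
                          check.names = FALSE),
               file.path(config$out_dir, "bray_curtis.tsv"))
    perm <- permanova(bc, diversity$role,
                      n_permutations = config$n_permutations,
                      seed = .stage_seed(config, "community"))
    tt <- compare_diversity(diversity$shannon[diversity$role == "mother"],
                            diversity$shannon[diversity$role == "infant"])
    res <- list(permanova = perm, diversity_t_test = tt)
    jsonlite::write_json(res, file.path(config$out_dir, "permanova.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })

  sharing <- stage("share", {
    dists <- do.call(rbind, lapply(inputs$alignments, function(a) {
      pair_distances(a, min_overlap = config$min_overlap)
    }))
    dists <- classify_pairs(dists, meta)
    dists <- normalize_distances(dists)
    .write_tsv(dists, file.path(config$out_dir, "pair_distances.tsv"))
    events <- call_shared_strains(dists, meta,
                                  threshold = config$sharing_threshold)
    .write_tsv(events, file.path(config$out_dir, "sharing_events.tsv"))
    summ <- summarize_sharing(events)
    .write_tsv(summ$table, file.path(config$out_dir, "sharing_summary.tsv"))
    tree_dir <- file.path(config$out_dir, "trees")
    dir.create(tree_dir, showWarnings = FALSE)
    for (sp in unique(events$species)) {
      sub <- dists[dists$species == sp, ]
      ids <- sort(unique(c(sub$sample_a, sub$sample_b)))
      if (length(ids) < 3) next
      m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
      m[cbind(match(sub$sample_a, ids), match(sub$sample_b, ids))] <-
        sub$jc_distance
      m <- m + t(m)
      writeLines(build_nj_tree(m), file.path(tree_dir, paste0(sp, ".nwk")))
    }
    list(events = events, summary = summ)
  })

  shifts <- stage("shift", {
    res <- shift_analysis(sharing$events, inputs$dna, inputs$rna, meta,
                          min_genes = config$min_genes,
                          act_threshold = config$activation_threshold,
                          deact_threshold = config$deactivation_threshold)
    rel <- do.call(rbind, lapply(seq_len(nrow(res$eligible)), function(i) {
      ev <- res$eligible[i, ]
      rbind(relative_expression(inputs$dna, inputs$rna, ev$species,
                                ev$mother_sample, config$min_genes),
            relative_expression(inputs$dna, inputs$rna, ev$species,
                                ev$infant_sample, config$min_genes))
    }))
    if (!is.null(rel))
      .write_tsv(rel, file.path(config$out_dir, "relative_expression.tsv"))
    .write_tsv(res$calls, file.path(config$out_dir, "shift_calls.tsv"))
    counts <- if (nrow(res$universe)) count_events(res$calls, res$universe)
              else list(per_species = data.frame(),
                        totals = list(activation_events = 0,
                                      deactivation_events = 0,
                                      universe_size = 0,
                                      activation_pct = NA_real_,
                                      deactivation_pct = NA_real_))
    .write_tsv(counts$per_species,
               file.path(config$out_dir, "shift_summary.tsv"))
    multi <- names(which(table(res$eligible$species) >= 2))
    reps <- data.frame(
      species = multi,
      replication_rate = vapply(multi, function(sp)
        replication_rate(res$calls, sp,
                         n_pairs = sum(res$eligible$species == sp)), 0),
      stringsAsFactors = FALSE)
    .write_tsv(reps, file.path(config$out_dir, "replication_rates.tsv"))
    ann <- if (nrow(res$universe) > 0)
      annotation_rate_test(res$calls, res$universe) else NULL
    if (!is.null(ann))
      jsonlite::write_json(
        list(p_activated = ann$p_activated,
             p_deactivated = ann$p_deactivated),
        file.path(config$out_dir, "annotation_test.json"),
        auto_unbox = TRUE, digits = NA)
    list(res = res, counts = counts, replication = reps, annotation = ann)
  })

  pathways <- stage("pathways", {
    out <- lapply(c(DNA = "pathways_dna", RNA = "pathways_rna"),
                  function(nm) {
      filt <- prevalence_filter(inputs[[nm]],
                                min_samples = config$min_samples)
      test_pathways(filt, meta)
    })
    .write_tsv(out$DNA, file.path(config$out_dir, "pathway_tests_dna.tsv"))
    .write_tsv(out$RNA, file.path(config$out_dir, "pathway_tests_rna.tsv"))
    out
  })

  summary <- list(
    n_shared_strains = sharing$summary$totals$n_strains,
    n_species = sharing$summary$totals$n_species,
    n_genera = sharing$summary$totals$n_genera,
    n_eligible_transcribed_strains = nrow(shifts$res$eligible),
    activation_events = shifts$counts$totals$activation_events,
    deactivation_events = shifts$counts$totals$deactivation_events,
    universe_size = shifts$counts$totals$universe_size,
    activation_pct = shifts$counts$totals$activation_pct,
    deactivation_pct = shifts$counts$totals$deactivation_pct,
    replication_rates = stats::setNames(
      as.list(shifts$replication$replication_rate),
      shifts$replication$species),
    permanova_R2 = community$permanova$R2,
    permanova_p = community$permanova$p,
    n_significant_pathways_dna = sum(pathways$DNA$significant),
    n_significant_pathways_rna = sum(pathways$RNA$significant))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("pipeline complete")
  invisible(summary)
}
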