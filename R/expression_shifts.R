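#' @title Transcriptional shifts of shared strains
#' @description The metatranscriptomic core of the workflow: per-gene-family
#'   RNA/DNA ratios normalized by the species-and-sample median ratio
#'   ("relative expression"), activation/deactivation calls for gene
#'   families on shared strains, event counting, replication rates across
#'   infants, and the annotated-fraction test.
#' @name expression_shifts
NULL

#' Scale raw counts to copies-per-million
#'
#' @param counts nonnegative numeric vector for one sample.
#' @param assume_cpm if `TRUE`, the input is already CPM and passes through
#'   untouched.
#' @return CPM values summing to 1e6 (unless `assume_cpm`).
#' @export
to_cpm <- function(counts, assume_cpm = FALSE) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (assume_cpm) return(counts)
  total <- sum(counts)
  if (total <= 0) stop("zero sample total", call. = FALSE)
  counts * 1e6 / total
}

# merged (dna, rna) entries for one (species, sample) stratum;
# genes with dna_cpm = 0 are excluded (their ratio is undefined),
# genes absent from the RNA table get rna_cpm = 0.
.stratum_ratios <- function(dna, rna, species, sample_id) {
  d <- dna[dna$species == species & dna$sample_id == sample_id &
             dna$cpm > 0, , drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  r <- rna[rna$species == species & rna$sample_id == sample_id, ,
           drop = FALSE]
  rna_cpm <- r$cpm[match(d$gene_family, r$gene_family)]
  rna_cpm[is.na(rna_cpm)] <- 0
  data.frame(species = species, sample_id = sample_id,
             gene_family = d$gene_family, dna_cpm = d$cpm,
             rna_cpm = rna_cpm, ratio = rna_cpm / d$cpm,
             stringsAsFactors = FALSE)
}

#' Relative expression of gene families in a (species, sample) stratum
#'
#' For every gene family of the species with `dna_cpm > 0` in the sample,
#' the RNA/DNA ratio is computed (genes with `rna_cpm = 0` get ratio 0 and
#' participate in the median); the stratum's `median_ratio` is the median
#' of those ratios and each gene's `relative_expression` is
#' `ratio / median_ratio`. Strata with fewer than `min_genes` eligible gene
#' families, or whose median ratio is zero, are excluded.
#'
#' @param dna,rna `gene_family_table`s (see [read_stratified_table()]).
#' @param species,sample_id stratum selectors; if both `NULL`, records for
#'   every stratum present in `dna` are returned.
#' @param min_genes minimum gene families with `dna_cpm > 0` per stratum.
#' @return data.frame with columns `species`, `sample_id`, `gene_family`,
#'   `dna_cpm`, `rna_cpm`, `ratio`, `median_ratio`, `relative_expression`.
#' @export
relative_expression <- function(dna, rna, species = NULL, sample_id = NULL,
                                min_genes = 10) {
  strata <- if (is.null(species) && is.null(sample_id)) {
    unique(dna[dna$cpm > 0, c("species", "sample_id")])
  } else {
    data.frame(species = species, sample_id = sample_id,
               stringsAsFactors = FALSE)
  }
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    rec <- .stratum_ratios(dna, rna, strata$species[i], strata$sample_id[i])
    if (is.null(rec) || nrow(rec) < min_genes) {
      message("stratum (", strata$species[i], ", ", strata$sample_id[i],
              ") excluded: fewer than ", min_genes, " gene families")
      next
    }
    med <- stats::median(rec$ratio)
    if (med == 0) {
      warning("median RNA/DNA ratio is zero for stratum (",
              strata$species[i], ", ", strata$sample_id[i],
              "); stratum excluded", call. = FALSE)
      next
    }
    rec$median_ratio <- med
    rec$relative_expression <- rec$ratio / med
    out[[i]] <- rec
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(species = character(), sample_id = character(),
                      gene_family = character(), dna_cpm = double(),
                      rna_cpm = double(), ratio = double(),
                      median_ratio = double(),
                      relative_expression = double())
  rownames(out) <- NULL
  out
}

# TRUE when the (species, sample) stratum passes the relative-expression
# preconditions: >= min_genes gene families with dna_cpm > 0 and a
# positive median RNA/DNA ratio.
.stratum_eligible <- function(dna, rna, species, sample_id, min_genes) {
  rec <- .stratum_ratios(dna, rna, species, sample_id)
  !is.null(rec) && nrow(rec) >= min_genes && stats::median(rec$ratio) > 0
}

#' Shared strains with a usable transcriptome signal
#'
#' Keeps sharing events where both the mother and the infant stratum pass
#' the [relative_expression()] preconditions, i.e. a relative-expression
#' profile can be computed on both sides of the dyad.
#'
#' @param events sharing events (see [call_shared_strains()]).
#' @param dna,rna `gene_family_table`s.
#' @param min_genes minimum gene families per stratum.
#' @return the subset of `events` that is eligible for shift calling.
#' @export
detect_shared_transcribed_strains <- function(events, dna, rna,
                                              min_genes = 10) {
  if (nrow(events) == 0) return(events)
  keep <- vapply(seq_len(nrow(events)), function(i) {
    .stratum_eligible(dna, rna, events$species[i], events$mother_sample[i],
                      min_genes) &&
      .stratum_eligible(dna, rna, events$species[i], events$infant_sample[i],
                        min_genes)
  }, TRUE)
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Activation/deactivation calls for one shared strain
#'
#' Compares relative expression between the infant and mother strata of one
#' (species, family). Only gene families with `dna_cpm > 0` in **both**
#' strata are compared. A gene family is `activated` when the infant
#' relative expression exceeds `act_threshold` and the infant/mother fold
#' exceeds `act_threshold`; `deactivated` when both fall below
#' `deact_threshold`; `neutral` otherwise. All comparisons are strict.
#' A mother relative expression of zero gives an infinite fold (activated
#' if the infant side qualifies); an infant relative expression of zero
#' gives fold zero.
#'
#' @param infant_records,mother_records relative-expression records of the
#'   same species for the infant and mother sample
#'   (see [relative_expression()]).
#' @param act_threshold,deact_threshold call thresholds (defaults 2, 0.5).
#' @return data.frame with `species`, `gene_family`, `infant_rel_expr`,
#'   `mother_rel_expr`, `fold`, `direction`.
#' @export
call_shifts <- function(infant_records, mother_records,
                        act_threshold = 2, deact_threshold = 0.5) {
  stopifnot(act_threshold > 1, deact_threshold < 1, deact_threshold > 0)
  common <- intersect(infant_records$gene_family,
                      mother_records$gene_family)
  inf <- infant_records[match(common, infant_records$gene_family), ]
  mot <- mother_records[match(common, mother_records$gene_family), ]
  fold <- ifelse(mot$relative_expression == 0,
                 ifelse(inf$relative_expression == 0, NaN, Inf),
                 inf$relative_expression / mot$relative_expression)
  direction <- rep("neutral", length(common))
  act <- inf$relative_expression > act_threshold & !is.nan(fold) &
    fold > act_threshold
  deact <- inf$relative_expression < deact_threshold & !is.nan(fold) &
    fold < deact_threshold
  direction[act] <- "activated"
  direction[deact] <- "deactivated"
  data.frame(species = inf$species, gene_family = common,
             infant_rel_expr = inf$relative_expression,
             mother_rel_expr = mot$relative_expression,
             fold = fold, direction = direction,
             stringsAsFactors = FALSE)
}

#' Shift calls across all eligible shared strains
#'
#' Driver combining [detect_shared_transcribed_strains()],
#' [relative_expression()] and [call_shifts()] over a whole cohort.
#'
#' @inheritParams detect_shared_transcribed_strains
#' @inheritParams call_shifts
#' @param metadata metadata data.frame; a family with more than one infant
#'   sample is an error (explicit sample selection is required).
#' @return list with `eligible` (events with a transcriptome signal),
#'   `calls` (one row per (species, family, gene family) comparison,
#'   including neutrals, with `family_id`) and `universe` (the compared
#'   gene families per (species, family)).
#' @export
shift_analysis <- function(events, dna, rna, metadata, min_genes = 10,
                           act_threshold = 2, deact_threshold = 0.5) {
  infants <- metadata[metadata$role == "infant", ]
  multi <- names(which(table(infants$family_id) > 1))
  if (length(multi))
    stop("family with multiple infant samples: ",
         paste(multi, collapse = ", "),
         "; select one sample per infant explicitly", call. = FALSE)
  eligible <- detect_shared_transcribed_strains(events, dna, rna, min_genes)
  calls <- vector("list", nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    inf <- relative_expression(dna, rna, eligible$species[i],
                               eligible$infant_sample[i], min_genes)
    mot <- relative_expression(dna, rna, eligible$species[i],
                               eligible$mother_sample[i], min_genes)
    cc <- call_shifts(inf, mot, act_threshold, deact_threshold)
    if (nrow(cc)) cc$family_id <- eligible$family_id[i]
    calls[[i]] <- cc
  }
  calls <- do.call(rbind, calls[vapply(calls, NROW, 0L) > 0])
  if (is.null(calls))
    calls <- data.frame(species = character(), gene_family = character(),
                        infant_rel_expr = double(), mother_rel_expr = double(),
                        fold = double(), direction = character(),
                        family_id = character())
  list(eligible = eligible,
       calls = calls,
       universe = calls[, c("species", "family_id", "gene_family")])
}

#' Count activation/deactivation events
#'
#' Per species: the number of activation and deactivation events (one per
#' (family, gene family) occurrence) and the number of unique activated /
#' deactivated gene families (a gene family activated in several infants
#' counts once). Overall percentages are relative to the gene-family
#' universe — all compared (species, family, gene family) tuples on the
#' eligible shared strains.
#'
#' @param calls shift calls (see [shift_analysis()]), with `family_id`.
#' @param universe data.frame of compared (species, family_id, gene_family)
#'   tuples defining the denominator.
#' @return list with `per_species` (data.frame) and `totals` (counts and
#'   percentages of the universe).
#' @export
count_events <- function(calls, universe) {
  if (nrow(universe) == 0) stop("empty gene-family universe", call. = FALSE)
  species <- sort(unique(universe$species))
  per <- lapply(species, function(sp) {
    cc <- calls[calls$species == sp, , drop = FALSE]
    act <- cc[cc$direction == "activated", , drop = FALSE]
    dea <- cc[cc$direction == "deactivated", , drop = FALSE]
    data.frame(species = sp,
               activation_events = nrow(act),
               deactivation_events = nrow(dea),
               unique_activated_families = length(unique(act$gene_family)),
               unique_deactivated_families = length(unique(dea$gene_family)),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  n_univ <- nrow(universe)
  totals <- list(
    activation_events = sum(per$activation_events),
    deactivation_events = sum(per$deactivation_events),
    universe_size = n_univ,
    activation_pct = sum(per$activation_events) / n_univ * 100,
    deactivation_pct = sum(per$deactivation_events) / n_univ * 100)
  list(per_species = per, totals = totals)
}

#' Replication rate of infant-activated gene families
#'
#' For one species with shared strains in two or more families: among the
#' unique gene families activated in at least one infant, the fraction
#' activated in two or more infants. `NA` when the species has fewer than
#' two family pairs.
#'
#' @param calls shift calls with `family_id`.
#' @param species species to evaluate.
#' @param n_pairs number of family pairs with calls for the species;
#'   inferred from `calls` when `NULL`.
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
replication_rate <- function(calls, species, n_pairs = NULL) {
  cc <- calls[calls$species == species, , drop = FALSE]
  if (is.null(n_pairs)) n_pairs <- length(unique(cc$family_id))
  if (n_pairs < 2) return(NA_real_)
  act <- cc[cc$direction == "activated", , drop = FALSE]
  if (nrow(act) == 0) return(NA_real_)
  per_gene <- table(unique(act[, c("gene_family", "family_id")])$gene_family)
  sum(per_gene >= 2) / length(per_gene)
}

# paired Wilcoxon signed-rank p-value; exact for <= 25 informative pairs
# (absent ties), normal approximation with continuity correction otherwise;
# all-zero differences give p = 1.
.paired_wilcoxon_p <- function(x, y) {
  diffs <- x - y
  nz <- diffs[diffs != 0]
  if (length(nz) == 0) return(1)
  use_exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  fit <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = use_exact,
                       correct = TRUE))
  fit$p.value
}

#' Annotated fraction of shifted vs all gene families, per strain
#'
#' For each shared strain (species, family), computes the percentage of
#' annotated gene families among all compared gene families, among the
#' activated ones and among the deactivated ones, and compares the shifted
#' percentages to the all-genes percentages with a paired Wilcoxon
#' signed-rank test across strains.
#'
#' @param calls shift calls with `family_id`.
#' @param universe compared (species, family_id, gene_family) tuples.
#' @inheritParams is_unannotated
#' @return list with `per_strain` (data.frame of paired percentages),
#'   `p_activated` and `p_deactivated`.
#' @export
annotation_rate_test <- function(calls, universe, annotation = NULL,
                                 unannotated_set = NULL,
                                 pattern = "_unknown$") {
  ann_pct <- function(genes) {
    if (length(genes) == 0) return(NA_real_)
    100 * mean(!is_unannotated(genes, annotation, unannotated_set, pattern))
  }
  strains <- unique(universe[, c("species", "family_id")])
  per <- lapply(seq_len(nrow(strains)), function(i) {
    in_strain <- universe$species == strains$species[i] &
      universe$family_id == strains$family_id[i]
    cc <- calls[calls$species == strains$species[i] &
                  calls$family_id == strains$family_id[i], , drop = FALSE]
    data.frame(
      species = strains$species[i], family_id = strains$family_id[i],
      all_pct = ann_pct(universe$gene_family[in_strain]),
      activated_pct = ann_pct(
        cc$gene_family[cc$direction == "activated"]),
      deactivated_pct = ann_pct(
        cc$gene_family[cc$direction == "deactivated"]),
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  test_against_all <- function(col) {
    ok <- !is.na(per[[col]]) & !is.na(per$all_pct)
    if (sum(ok) < 2) return(NA_real_)
    .paired_wilcoxon_p(per[[col]][ok], per$all_pct[ok])
  }
  list(per_strain = per,
       p_activated = test_against_all("activated_pct"),
       p_deactivated = test_against_all("deactivated_pct"))
}
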