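#' @title Strain sharing between mothers and infants
#' @description Pairwise SNP-haplotype distances per species, Jukes-Cantor
#'   correction, per-species median normalization, and shared-strain calls
#'   for within-family mother-infant pairs.
#' @name strain_sharing
NULL

#' Observed proportion of differing sites between two aligned haplotypes
#'
#' Alignment columns where either sequence carries a gap (`-`) or an
#' ambiguous base (`N`) are excluded; `p` is the mismatch fraction over the
#' remaining sites.
#'
#' @param seq_a,seq_b aligned sequences of equal length over `{A,C,G,T,N,-}`.
#' @return list with `p` (fraction) and `n_sites` (compared sites).
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b))
    stop("sequences differ in length", call. = FALSE)
  valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n_sites <- sum(valid)
  p <- if (n_sites == 0) NA_real_ else sum(a[valid] != b[valid]) / n_sites
  list(p = p, n_sites = n_sites)
}

#' Jukes-Cantor distance
#'
#' Corrects an observed p-distance for multiple substitutions:
#' d = -(3/4) log(1 - (4/3) p), valid for p in `[0, 0.75)`.
#'
#' @param p observed proportion(s) of differing sites.
#' @return substitutions per site.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0 | p >= 0.75))
    stop("Jukes-Cantor distance undefined for p outside [0, 0.75)",
         call. = FALSE)
  -0.75 * log(1 - (4 / 3) * p)
}

#' All pairwise haplotype distances for one species
#'
#' @param alignment a `haplotype_alignment`.
#' @param min_overlap minimum compared sites to accept a pair; pairs below
#'   are dropped with a warning.
#' @return data.frame with one row per retained sample pair: `species`,
#'   `sample_a`, `sample_b`, `p_distance`, `n_sites`, `jc_distance`.
#' @export
pair_distances <- function(alignment, min_overlap = 100) {
  seqs <- alignment$sequences
  ids <- names(seqs)
  if (length(seqs) < 2)
    stop("need >= 2 sequences for distances", call. = FALSE)
  chars <- do.call(rbind, strsplit(seqs, ""))
  ok <- chars == "A" | chars == "C" | chars == "G" | chars == "T"
  pairs <- utils::combn(length(seqs), 2)
  n_dropped <- 0L
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    valid <- ok[i, ] & ok[j, ]
    n_sites <- sum(valid)
    if (n_sites < min_overlap) { n_dropped <- n_dropped + 1L; next }
    p <- sum(chars[i, valid] != chars[j, valid]) / n_sites
    if (p >= 0.75) {
      warning("saturated distance (p >= 0.75) between ", ids[i], " and ",
              ids[j], " for ", alignment$species, "; pair skipped",
              call. = FALSE)
      next
    }
    rows[[k]] <- data.frame(
      species = alignment$species, sample_a = ids[i], sample_b = ids[j],
      p_distance = p, n_sites = n_sites,
      jc_distance = jukes_cantor(p), stringsAsFactors = FALSE)
  }
  if (n_dropped > 0)
    warning(n_dropped, " pair(s) below min_overlap of ", min_overlap,
            " sites skipped for ", alignment$species, call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(species = character(), sample_a = character(),
                      sample_b = character(), p_distance = double(),
                      n_sites = integer(), jc_distance = double())
  out
}

#' Classify sample pairs against the metadata
#'
#' A pair is `within_family_mother_infant` when both samples belong to the
#' same family and one is from the mother, the other from the infant; all
#' other pairs are `other`.
#'
#' @param distances data.frame from [pair_distances()].
#' @param metadata metadata data.frame (see [read_metadata()]).
#' @return `distances` with columns `pair_class` and `family_id` added
#'   (`family_id` is `NA` for `other` pairs).
#' @export
classify_pairs <- function(distances, metadata) {
  ia <- match(distances$sample_a, metadata$sample_id)
  ib <- match(distances$sample_b, metadata$sample_id)
  if (anyNA(ia) || anyNA(ib))
    stop("sample in distance table absent from metadata", call. = FALSE)
  same_family <- metadata$family_id[ia] == metadata$family_id[ib]
  dyad <- metadata$role[ia] != metadata$role[ib]
  wf <- same_family & dyad
  distances$pair_class <- ifelse(wf, "within_family_mother_infant", "other")
  distances$family_id <- ifelse(wf, metadata$family_id[ia], NA_character_)
  distances
}

#' Median-normalize Jukes-Cantor distances per species
#'
#' Each pair's JC distance is divided by the per-species median over all
#' pairwise JC distances (within-family and other pairs pooled), so 0 means
#' identical haplotypes and 1 the species' median dissimilarity. Species
#' whose median distance is zero (all strains identical) are excluded with
#' a warning.
#'
#' @param distances data.frame with columns `species` and `jc_distance`
#'   (possibly covering several species).
#' @return `distances` with a `normalized_distance` column; rows of excluded
#'   species removed.
#' @export
normalize_distances <- function(distances) {
  parts <- split(distances, distances$species)
  out <- lapply(parts, function(d) {
    if (nrow(d) < 2) {
      warning("species ", d$species[1],
              " has < 2 pairwise distances; excluded", call. = FALSE)
      return(NULL)
    }
    med <- stats::median(d$jc_distance)
    if (med == 0) {
      warning("median distance is zero for ", d$species[1],
              "; species excluded from normalization", call. = FALSE)
      return(NULL)
    }
    d$normalized_distance <- d$jc_distance / med
    d
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    out <- distances[0, ]
    out$normalized_distance <- double(0)
  }
  rownames(out) <- NULL
  out
}

#' Call strains shared within mother-infant pairs
#'
#' A within-family mother-infant pair whose median-normalized distance is
#' at or below `threshold` (default 0.2) is called a shared strain; at most
#' one event is kept per (species, family), the one with the smallest
#' normalized distance.
#'
#' @param distances normalized, classified distance table
#'   (see [normalize_distances()], [classify_pairs()]).
#' @param metadata metadata data.frame.
#' @param threshold sharing threshold on the normalized distance.
#' @param inclusive compare with `<=` (default) rather than `<`.
#' @return data.frame of sharing events: `species`, `family_id`,
#'   `mother_sample`, `infant_sample`, `normalized_distance`,
#'   `breastfeeding`.
#' @export
call_shared_strains <- function(distances, metadata, threshold = 0.2,
                                inclusive = TRUE) {
  if (is.null(distances$pair_class))
    distances <- classify_pairs(distances, metadata)
  if (is.null(distances$normalized_distance))
    stop("normalized distances missing; run normalize_distances() first",
         call. = FALSE)
  wf <- distances[distances$pair_class == "within_family_mother_infant", ,
                  drop = FALSE]
  hit <- if (inclusive) wf$normalized_distance <= threshold
         else wf$normalized_distance < threshold
  wf <- wf[hit, , drop = FALSE]
  if (nrow(wf) == 0)
    return(data.frame(species = character(), family_id = character(),
                      mother_sample = character(), infant_sample = character(),
                      normalized_distance = double(),
                      breastfeeding = character()))
  role_a <- metadata$role[match(wf$sample_a, metadata$sample_id)]
  wf$mother_sample <- ifelse(role_a == "mother", wf$sample_a, wf$sample_b)
  wf$infant_sample <- ifelse(role_a == "mother", wf$sample_b, wf$sample_a)
  wf$breastfeeding <-
    metadata$breastfeeding[match(wf$infant_sample, metadata$sample_id)]
  # one event max per (species, family): keep the closest pair
  wf <- wf[order(wf$species, wf$family_id, wf$normalized_distance), ]
  wf <- wf[!duplicated(wf[, c("species", "family_id")]), ]
  rownames(wf) <- NULL
  wf[, c("species", "family_id", "mother_sample", "infant_sample",
         "normalized_distance", "breastfeeding")]
}

#' Summarize sharing events per species
#'
#' Produces the per-species event table (total events and counts per
#' breastfeeding status) plus cohort totals: number of shared strains,
#' number of species and number of genera (genus = first `_`- or
#' whitespace-delimited token of the species name).
#'
#' @param events sharing-event data.frame with columns `species`,
#'   `family_id` (or one row per event) and `breastfeeding`.
#' @return list with `table` (per-species data.frame sorted by descending
#'   event count) and `totals` (`n_strains`, `n_species`, `n_genera`).
#' @export
summarize_sharing <- function(events) {
  if (nrow(events) == 0)
    return(list(table = data.frame(species = character(), total = integer(),
                                   exclusive = integer(), partial = integer(),
                                   none = integer(), unknown = integer()),
                totals = list(n_strains = 0L, n_species = 0L, n_genera = 0L)))
  bf <- factor(events$breastfeeding, levels = .breastfeeding_levels)
  counts <- table(events$species, bf)
  tab <- data.frame(species = rownames(counts),
                    total = as.integer(rowSums(counts)),
                    exclusive = as.integer(counts[, "exclusive"]),
                    partial = as.integer(counts[, "partial"]),
                    none = as.integer(counts[, "none"]),
                    unknown = as.integer(counts[, "unknown"]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$total, tab$species), ]
  rownames(tab) <- NULL
  list(table = tab,
       totals = list(n_strains = sum(tab$total),
                     n_species = nrow(tab),
                     n_genera = length(unique(genus_of(tab$species)))))
}

#' Genus of a species name
#'
#' First token of the species name, splitting on underscore or whitespace.
#'
#' @param species character vector of species names.
#' @export
genus_of <- function(species) {
  vapply(strsplit(species, "[_[:space:]]+"), `[`, "", 1)
}

#' Read an aggregated per-species sharing-event table
#'
#' Parses a TSV with columns `species`, `total`, `exclusive`, `partial`,
#' `none` — the shape of a published per-species transmission-event table —
#' and checks that breastfeeding counts add up to the totals.
#'
#' @param path path to the TSV.
#' @export
read_sharing_counts <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("species", "total", "exclusive", "partial", "none") %in%
                  names(df)))
  bad <- df$total != df$exclusive + df$partial + df$none
  if (any(bad))
    stop("breastfeeding counts do not sum to total for: ",
         paste(df$species[bad], collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_sharing_counts
#' @param counts aggregated table from [read_sharing_counts()].
#' @return one row per event with `species`, `family_id` (synthetic ids,
#'   one per event) and `breastfeeding`, suitable for [summarize_sharing()].
#' @export
expand_sharing_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    bf <- rep(c("exclusive", "partial", "none"),
              times = c(counts$exclusive[i], counts$partial[i],
                        counts$none[i]))
    if (length(bf) == 0) return(NULL)
    data.frame(species = counts$species[i],
               breastfeeding = bf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  out$family_id <- sprintf("F%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("species", "family_id", "breastfeeding")]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds an unrooted neighbor-joining tree; negative branch lengths are
#' clamped to zero. Returns the tree in newick format.
#'
#' @param dist symmetric distance matrix with >= 3 samples.
#' @return single-element character vector: the newick string.
#' @export
build_nj_tree <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 3) stop("need >= 3 samples for a tree", call. = FALSE)
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  ape::write.tree(tree)
}
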