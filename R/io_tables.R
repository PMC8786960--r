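#' @title Input/output for cohort tables
#' @description Readers, writers and validators for the five input kinds the
#'   workflow consumes: sample metadata, taxonomic relative-abundance
#'   profiles, species-stratified gene-family CPM tables (DNA and RNA),
#'   pathway abundance tables, and per-species SNP-haplotype alignments.
#'   All tabular formats are tab-separated UTF-8 with a header line;
#'   lines starting with `#` are treated as comments.
#' @name io_tables
NULL

.roles <- c("mother", "infant")
.breastfeeding_levels <- c("exclusive", "partial", "none", "unknown")

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

#' Read sample metadata
#'
#' Parses a metadata TSV with required columns `sample_id`, `family_id` and
#' `role` (`mother`/`infant`). An optional `breastfeeding` column takes
#' values `exclusive`, `partial`, `none` or `unknown` (defaulting to
#' `unknown` when the column is absent); an optional `site` column carries
#' the collection site.
#'
#' @param path path to a tab-separated metadata file.
#' @return a data.frame with columns `sample_id`, `family_id`, `role`,
#'   `breastfeeding`, `site`; one row per sample.
#' @export
read_metadata <- function(path) {
  df <- .read_tsv(path)
  required <- c("sample_id", "family_id", "role")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$family_id <- as.character(df$family_id)
  df$role <- as.character(df$role)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in metadata: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  bad_role <- setdiff(unique(df$role), .roles)
  if (length(bad_role))
    stop("unknown role value(s): ", paste(bad_role, collapse = ", "),
         "; expected mother or infant", call. = FALSE)
  if (is.null(df$breastfeeding)) {
    df$breastfeeding <- "unknown"
  } else {
    df$breastfeeding <- as.character(df$breastfeeding)
    df$breastfeeding[is.na(df$breastfeeding) | df$breastfeeding == ""] <- "unknown"
    bad_bf <- setdiff(unique(df$breastfeeding), .breastfeeding_levels)
    if (length(bad_bf))
      stop("unknown breastfeeding value(s): ",
           paste(bad_bf, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$site)) df$site <- NA_character_
  df[, c("sample_id", "family_id", "role", "breastfeeding", "site")]
}

#' @rdname read_metadata
#' @param metadata a metadata data.frame as returned by [read_metadata()].
#' @export
write_metadata <- function(metadata, path) {
  .write_tsv(metadata, path)
  invisible(path)
}

#' Read a taxonomic relative-abundance profile
#'
#' The on-disk layout follows taxonomic profilers: rows are species, columns
#' are samples, the first column (`species`) holds the species name. Values
#' may be fractions (rows of the returned matrix summing to 1) or
#' percentages (summing to 100); percentage profiles are rescaled to
#' fractions on read.
#'
#' @param path path to a tab-separated species-by-sample table.
#' @return numeric matrix, rows = samples, columns = species, each row
#'   summing to 1.
#' @export
read_taxonomic_profile <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("taxonomic profile needs species + sample columns",
                         call. = FALSE)
  species <- as.character(df[[1]])
  mat <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(mat) <- species
  storage.mode(mat) <- "double"
  validate_taxonomic_profile(mat)
}

#' @rdname read_taxonomic_profile
#' @param profile samples-by-species matrix of relative abundances.
#' @export
write_taxonomic_profile <- function(profile, path) {
  df <- data.frame(species = colnames(profile), t(profile),
                   check.names = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname read_taxonomic_profile
#' @param tol tolerance on the row-sum invariant.
#' @export
validate_taxonomic_profile <- function(profile, tol = 1e-6) {
  if (any(profile < 0)) stop("negative relative abundance", call. = FALSE)
  sums <- rowSums(profile)
  if (any(sums <= 0)) stop("sample with all-zero profile", call. = FALSE)
  # accept the 0-100 convention and rescale
  pct <- abs(sums - 100) <= 100 * tol
  profile[pct, ] <- profile[pct, , drop = FALSE] / 100
  sums <- rowSums(profile)
  off <- abs(sums - 1) > tol
  if (any(off))
    stop("taxonomic profile rows do not sum to 1 (or 100): sample(s) ",
         paste(rownames(profile)[off], collapse = ", "), call. = FALSE)
  profile / sums
}

#' Read a species-stratified gene-family table
#'
#' Parses the stratified dialect of functional profilers: the first column
#' holds `GeneFamilyID|Species` keys (unstratified `GeneFamilyID` rows are
#' dropped with a message), remaining columns are samples, values are
#' copies-per-million (CPM).
#'
#' @param path path to the stratified TSV.
#' @param molecule `"DNA"` or `"RNA"`; recorded as an attribute.
#' @param sep stratification separator between gene family and species.
#' @return a long-format data.frame of class `gene_family_table` with
#'   columns `sample_id`, `species`, `gene_family`, `cpm` and attribute
#'   `molecule`.
#' @export
read_stratified_table <- function(path, molecule = c("DNA", "RNA"),
                                  sep = "|") {
  molecule <- match.arg(molecule)
  df <- .read_tsv(path)
  keys <- as.character(df[[1]])
  samples <- names(df)[-1]
  parts <- strsplit(keys, sep, fixed = TRUE)
  n_fields <- lengths(parts)
  unstrat <- n_fields == 1
  if (any(unstrat))
    message(sum(unstrat), " unstratified row(s) dropped")
  malformed <- n_fields > 2
  if (any(malformed)) {
    warning(sum(malformed), " row(s) with malformed stratification rejected",
            call. = FALSE)
  }
  keep <- n_fields == 2
  df <- df[keep, , drop = FALSE]
  parts <- parts[keep]
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative CPM at row ", neg[1, 1], ", sample ",
         samples[neg[1, 2]], call. = FALSE)
  long <- data.frame(
    sample_id   = rep(samples, each = nrow(vals)),
    gene_family = rep(vapply(parts, `[`, "", 1), times = length(samples)),
    species     = rep(vapply(parts, `[`, "", 2), times = length(samples)),
    cpm         = as.vector(vals),
    stringsAsFactors = FALSE
  )
  gene_family_table(long, molecule)
}

#' Construct a gene-family table from long-format entries
#'
#' @param entries data.frame with columns `sample_id`, `species`,
#'   `gene_family`, `cpm`.
#' @param molecule `"DNA"` or `"RNA"`.
#' @param cpm_tol tolerance on the per-sample total-CPM bound.
#' @export
gene_family_table <- function(entries, molecule = c("DNA", "RNA"),
                              cpm_tol = 1e-6) {
  molecule <- match.arg(molecule)
  stopifnot(all(c("sample_id", "species", "gene_family", "cpm") %in%
                  names(entries)))
  if (any(entries$cpm < 0)) stop("negative CPM value", call. = FALSE)
  totals <- tapply(entries$cpm, entries$sample_id, sum)
  if (any(totals > 1e6 * (1 + cpm_tol)))
    stop("per-sample CPM total exceeds 1e6 for sample(s): ",
         paste(names(totals)[totals > 1e6 * (1 + cpm_tol)], collapse = ", "),
         call. = FALSE)
  entries <- entries[, c("sample_id", "species", "gene_family", "cpm")]
  attr(entries, "molecule") <- molecule
  class(entries) <- c("gene_family_table", "data.frame")
  entries
}

#' @rdname read_stratified_table
#' @param tab a `gene_family_table`.
#' @export
write_stratified_table <- function(tab, path, sep = "|") {
  key <- paste(tab$gene_family, tab$species, sep = sep)
  samples <- sort(unique(tab$sample_id))
  keys <- sort(unique(key))
  wide <- matrix(0, nrow = length(keys), ncol = length(samples),
                 dimnames = list(keys, samples))
  wide[cbind(match(key, keys), match(tab$sample_id, samples))] <- tab$cpm
  df <- data.frame(gene_family = keys, wide, check.names = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Read a pathway abundance table
#'
#' Rows on disk are pathways (MetaCyc-style identifiers in the first
#' column), columns are samples; values are nonnegative abundances.
#'
#' @param path path to the pathway TSV.
#' @param molecule `"DNA"` or `"RNA"`.
#' @return samples-by-pathways numeric matrix with attribute `molecule`.
#' @export
read_pathway_table <- function(path, molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  df <- .read_tsv(path)
  ids <- as.character(df[[1]])
  if (any(!nzchar(ids))) stop("empty pathway_id", call. = FALSE)
  mat <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(mat) <- ids
  storage.mode(mat) <- "double"
  if (any(mat < 0)) stop("negative pathway abundance", call. = FALSE)
  attr(mat, "molecule") <- molecule
  mat
}

#' @rdname read_pathway_table
#' @param table samples-by-pathways matrix.
#' @export
write_pathway_table <- function(table, path) {
  df <- data.frame(pathway_id = colnames(table), t(table),
                   check.names = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Read a per-species SNP-haplotype alignment
#'
#' One FASTA record per sample (record id = sample id), all records the
#' same length; sequences are uppercased on read. Alphabet `{A,C,G,T,N,-}`.
#'
#' @param path path to the FASTA alignment.
#' @param species species the alignment belongs to.
#' @return a list of class `haplotype_alignment` with elements `species`,
#'   `sequences` (named character vector) and `alignment_length`.
#' @export
read_alignment <- function(path, species) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bin <- ape::read.FASTA(path)
  if (length(bin) == 0) stop("empty alignment file: ", path, call. = FALSE)
  seqs <- vapply(as.character(bin),
                 function(s) paste(toupper(s), collapse = ""), "")
  haplotype_alignment(species, seqs)
}

#' @rdname read_alignment
#' @param sequences named character vector of aligned sequences.
#' @export
haplotype_alignment <- function(species, sequences) {
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1)
    stop("ragged alignment for ", species, ": lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("non-ACGTN- characters in alignment for ", species, call. = FALSE)
  structure(list(species = species, sequences = sequences,
                 alignment_length = unname(lens[1])),
            class = "haplotype_alignment")
}

#' @rdname read_alignment
#' @param alignment a `haplotype_alignment`.
#' @export
write_alignment <- function(alignment, path) {
  bin <- ape::as.DNAbin(strsplit(alignment$sequences, ""))
  names(bin) <- names(alignment$sequences)
  ape::write.FASTA(bin, path)
  invisible(path)
}

#' Gene-family annotation status
#'
#' A gene family is "unannotated" when its id is in `unannotated_set`, or
#' matches `pattern` (default: ids ending in `_unknown`); an explicit
#' two-column annotation table (`gene_family`, `annotated` in
#' `{annotated, unannotated}`) overrides both.
#'
#' @param gene_family character vector of gene-family ids.
#' @param annotation optional data.frame from [read_annotation()].
#' @param unannotated_set optional character vector of unannotated ids.
#' @param pattern regular expression marking unannotated ids.
#' @return logical vector, `TRUE` where the gene family is unannotated.
#' @export
is_unannotated <- function(gene_family, annotation = NULL,
                           unannotated_set = NULL,
                           pattern = "_unknown$") {
  out <- grepl(pattern, gene_family)
  if (!is.null(unannotated_set))
    out <- out | gene_family %in% unannotated_set
  if (!is.null(annotation)) {
    idx <- match(gene_family, annotation$gene_family)
    hit <- !is.na(idx)
    out[hit] <- annotation$annotated[idx[hit]] == "unannotated"
  }
  out
}

#' @rdname is_unannotated
#' @param path two-column TSV (`gene_family`, `annotated`).
#' @export
read_annotation <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("gene_family", "annotated") %in% names(df)))
    stop("annotation table needs columns gene_family, annotated",
         call. = FALSE)
  bad <- setdiff(unique(df$annotated), c("annotated", "unannotated"))
  if (length(bad))
    stop("unknown annotation status: ", paste(bad, collapse = ", "),
         call. = FALSE)
  df
}
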