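#' Prevalence filter for pathway tables
#'
#' Keeps pathways observed (abundance > 0) in at least `min_samples`
#' samples.
#'
#' @param table samples-by-pathways matrix (see [read_pathway_table()]).
#' @param min_samples minimum samples with nonzero abundance (default 2).
#' @return the filtered matrix (possibly with zero columns).
#' @export
prevalence_filter <- function(table, min_samples = 2) {
  keep <- colSums(table > 0) >= min_samples
  out <- table[, keep, drop = FALSE]
  attr(out, "molecule") <- attr(table, "molecule")
  out
}

#' Mother-vs-infant differential abundance of pathways
#'
#' Per pathway, fits `log10(abundance + pseudocount) ~ role + (1 | family)`
#' — role (mother/infant) as the fixed effect, family as a random intercept
#' — and reports the two-sided p-value for the role effect
#' (Satterthwaite degrees of freedom), BH-adjusted q-values over the tested
#' pathways, and the effect direction from the sign of the role
#' coefficient. Pathways constant across samples are skipped with a
#' warning; if the mixed fit fails, a fixed-effects linear model is used
#' with a message.
#'
#' @param table samples-by-pathways matrix, typically after
#'   [prevalence_filter()].
#' @param metadata metadata data.frame covering the table's samples.
#' @param pseudocount added before the log10 transform; default is half the
#'   smallest nonzero value in the table.
#' @param q_threshold significance threshold on the q-value (default 0.05).
#' @return data.frame with one row per tested pathway: `pathway_id`,
#'   `molecule`, `n_samples_observed`, `direction`
#'   (`higher_in_mothers`/`higher_in_infants`), `p`, `q`, `significant`.
#' @export
test_pathways <- function(table, metadata, pseudocount = NULL,
                          q_threshold = 0.05) {
  samples <- rownames(table)
  idx <- match(samples, metadata$sample_id)
  if (anyNA(idx)) stop("sample missing from metadata", call. = FALSE)
  role <- factor(metadata$role[idx], levels = c("mother", "infant"))
  family <- factor(metadata$family_id[idx])
  if (length(unique(role)) < 2)
    stop("both roles required for testing", call. = FALSE)
  if (is.null(pseudocount)) {
    nz <- table[table > 0]
    if (length(nz) == 0) stop("all-zero pathway table", call. = FALSE)
    pseudocount <- min(nz) / 2
  }
  rows <- lapply(colnames(table), function(pw) {
    y <- table[, pw]
    if (stats::sd(y) == 0) {
      warning("pathway ", pw, " constant across samples; skipped",
              call. = FALSE)
      return(NULL)
    }
    ly <- log10(y + pseudocount)
    dat <- data.frame(ly = ly, role = role, family = family)
    coefs <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(ly ~ role + (1 | family), data = dat)))
      stats::coef(summary(fit))["roleinfant",
                                c("Estimate", "Pr(>|t|)")]
    }, error = function(e) {
      message("mixed fit failed for ", pw, " (", conditionMessage(e),
              "); falling back to a fixed-effects linear model")
      fit <- stats::lm(ly ~ role, data = dat)
      stats::coef(summary(fit))["roleinfant", c("Estimate", "Pr(>|t|)")]
    })
    data.frame(pathway_id = pw,
               molecule = attr(table, "molecule") %||% NA_character_,
               n_samples_observed = sum(y > 0),
               direction = if (coefs[1] > 0) "higher_in_infants"
                           else "higher_in_mothers",
               p = unname(coefs[2]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(pathway_id = character(), molecule = character(),
                      n_samples_observed = integer(), direction = character(),
                      p = double(), q = double(), significant = logical()))
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < q_threshold
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up q-values
#'
#' q_(i) = min over j >= i of p_(j) * n / j, capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}
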