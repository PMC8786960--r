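#' Shannon diversity of one abundance profile
#'
#' H = -sum p_i log(p_i) in nats, computed after renormalizing the profile
#' to sum to one; zero-abundance species contribute nothing.
#'
#' @param abundances nonnegative numeric vector, sum > 0.
#' @return Shannon index in nats.
#' @export
shannon_diversity <- function(abundances) {
  if (any(abundances < 0)) stop("negative abundance", call. = FALSE)
  if (sum(abundances) <= 0) stop("all-zero profile", call. = FALSE)
  p <- abundances / sum(abundances)
  unname(vegan::diversity(p, index = "shannon"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(a, b) = 1 - 2 sum_i min(a_i, b_i) / (sum a_i + sum b_i) over all
#' pairs of samples in a samples-by-species profile.
#'
#' @param profile samples-by-species abundance matrix, >= 2 rows.
#' @return symmetric dissimilarity matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
bray_curtis <- function(profile) {
  profile <- as.matrix(profile)
  if (nrow(profile) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(rowSums(profile) <= 0))
    stop("sample with zero total abundance", call. = FALSE)
  as.matrix(vegan::vegdist(profile, method = "bray"))
}

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate ANOVA. The pseudo-F statistic is
#' built from the among/within decomposition of squared dissimilarities:
#' SS_total = sum of squared distances / n, SS_within analogous per group,
#' SS_among = SS_total - SS_within, F = (SS_among/(a-1)) / (SS_within/(n-a)).
#' The p-value is the permutation tail probability
#' (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations), with ties counted as
#' exceeding (conservative).
#'
#' @param dist symmetric dissimilarity matrix (or `dist`).
#' @param groups group label per sample, >= 2 groups of >= 2 samples.
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return list with `R2`, `p`, `F`, `n_permutations`.
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length != number of samples",
                                call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2)) stop("every group needs >= 2 samples", call. = FALSE)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- function(g) {
    sum(vapply(unique(g), function(lv) {
      idx <- which(g == lv)
      sub <- d2[idx, idx, drop = FALSE]
      sum(sub[upper.tri(sub)]) / length(idx)
    }, 0))
  }
  a <- length(sizes)
  sw <- ss_within(groups)
  if (sw <= 0 && ss_total <= 0)
    stop("constant distances: PERMANOVA undefined", call. = FALSE)
  f_stat <- function(sw) ((ss_total - sw) / (a - 1)) / (sw / (n - a))
  f_obs <- f_stat(sw)
  if (!is.finite(f_obs))
    stop("zero within-group variation: pseudo-F undefined", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  exceed <- 0L
  for (i in seq_len(n_permutations)) {
    fp <- f_stat(ss_within(sample(groups)))
    if (fp >= f_obs) exceed <- exceed + 1L
  }
  list(R2 = (ss_total - sw) / ss_total,
       F = f_obs,
       p = (1 + exceed) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' Compare diversity between two groups
#'
#' Equal-variance two-sample (Student's) t-test on per-sample diversity
#' values.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list with `t` and `p`.
#' @export
compare_diversity <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs >= 2 values", call. = FALSE)
  if (stats::var(values_a) + stats::var(values_b) == 0)
    stop("zero pooled variance", call. = FALSE)
  fit <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value)
}
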