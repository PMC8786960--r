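# Independent oracles used to freeze expected values: direct evaluations of
# the defining formulas, kept free of the package's code paths.

# Bray-Curtis by double loop over the defining formula
bc_brute <- function(profile) {
  n <- nrow(profile)
  out <- matrix(0, n, n, dimnames = list(rownames(profile),
                                         rownames(profile)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- profile[i, ]; b <- profile[j, ]
    out[i, j] <- 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
  }
  out
}

# Benjamini-Hochberg step-up, written from the definition
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# all permutations of a vector (n! rows); n kept tiny in tests
all_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)
  }))
}

# pseudo-F computed directly from the squared-distance decomposition
pseudo_f <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  a <- length(unique(groups))
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# exact PERMANOVA p by enumerating every label permutation
permanova_exact_p <- function(d, groups) {
  f_obs <- pseudo_f(d, groups)
  perms <- all_perms(seq_along(groups))
  fs <- apply(perms, 1, function(ix) pseudo_f(d, groups[ix]))
  mean(fs >= f_obs - 1e-12)
}

# exact two-sided signed-rank p by enumerating all sign assignments
# (differences assumed nonzero with distinct magnitudes)
signed_rank_exact_p <- function(diffs) {
  stopifnot(all(diffs != 0), !any(duplicated(abs(diffs))))
  n <- length(diffs)
  ranks <- rank(abs(diffs))
  w_obs <- sum(ranks[diffs > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% ranks)
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}
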