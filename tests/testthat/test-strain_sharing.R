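test_that("p-distance excludes gap/N columns and counts sites", {
  expect_equal(p_distance("AAAA", "AAAA"), list(p = 0, n_sites = 4))
  expect_equal(p_distance("AAAA", "AAAT"), list(p = 0.25, n_sites = 4))
  expect_equal(p_distance("AA-A", "AATA"), list(p = 0, n_sites = 3))
  expect_equal(p_distance("ANAA", "AAAA")$n_sites, 3)
  expect_error(p_distance("AAA", "AAAA"), "length")
})

test_that("Jukes-Cantor correction matches its closed form and domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.25), -0.75 * log(2 / 3))
  expect_equal(jukes_cantor(0.25), 0.30410, tolerance = 1e-5)
  expect_error(jukes_cantor(0.75), "0.75")
  expect_error(jukes_cantor(-0.01), "0.75")
  # strictly increasing, and jc >= p with equality only at zero
  p <- seq(0, 0.74, by = 0.01)
  d <- jukes_cantor(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d[-1] > p[-1]))
})

test_that("pairwise distances agree with ape's pairwise-deletion distances", {
  set.seed(4)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, 300, replace = TRUE)
  seqs <- vapply(1:4, function(i) {
    ch <- anc
    mut <- runif(300) < 0.1
    ch[mut] <- sample(bases, sum(mut), replace = TRUE)
    ch[runif(300) < 0.04] <- "-"
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- paste0("s", 1:4)
  aln <- haplotype_alignment("spX", seqs)
  got <- pair_distances(aln, min_overlap = 10)
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  p_ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                   pairwise.deletion = TRUE))
  jc_ref <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                    pairwise.deletion = TRUE))
  for (k in seq_len(nrow(got))) {
    expect_equal(got$p_distance[k], p_ref[got$sample_a[k], got$sample_b[k]],
                 tolerance = 1e-12)
    expect_equal(got$jc_distance[k],
                 jc_ref[got$sample_a[k], got$sample_b[k]],
                 tolerance = 1e-12)
  }
  # min_overlap drops short-overlap pairs with a warning, not an error
  expect_warning(out <- pair_distances(aln, min_overlap = 1000),
                 "min_overlap")
  expect_equal(nrow(out), 0)
})

test_that("median normalization scales each species to unit median", {
  d <- data.frame(species = "sp",
                  sample_a = c("a", "a", "b"), sample_b = c("b", "c", "c"),
                  p_distance = NA, n_sites = 300,
                  jc_distance = c(0.01, 0.02, 0.03))
  out <- normalize_distances(d)
  expect_equal(out$normalized_distance, c(0.5, 1.0, 1.5))
  d$jc_distance <- rep(0.02, 3)
  expect_equal(normalize_distances(d)$normalized_distance, rep(1, 3))
  d$jc_distance <- rep(0, 3)
  expect_warning(out0 <- normalize_distances(d), "zero")
  expect_equal(nrow(out0), 0)
  # odd pair count: median of normalized values is exactly 1
  set.seed(8)
  d5 <- d[rep(1, 5), ]; d5$jc_distance <- runif(5, 0.001, 0.1)
  expect_equal(median(normalize_distances(d5)$normalized_distance), 1)
})

test_that("shared-strain calls honor the threshold, dyad rule and dedup", {
  meta <- make_metadata(2)
  d <- data.frame(
    species = "sp",
    sample_a = c("M01", "M01", "M02", "M01"),
    sample_b = c("I01", "I02", "I02", "M02"),
    p_distance = NA, n_sites = 300,
    jc_distance = NA,
    normalized_distance = c(0.05, 0.5, 0.2, 0.01))
  ev <- call_shared_strains(d, meta, threshold = 0.2)
  # M01-I01 (0.05) shared; M01-I02 crosses families; M02-I02 at the
  # inclusive boundary shared; M01-M02 same-role pair never called
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$family_id, c("F01", "F02"))
  expect_equal(ev$normalized_distance[ev$family_id == "F02"], 0.2)
  ev_strict <- call_shared_strains(d, meta, threshold = 0.2,
                                   inclusive = FALSE)
  expect_equal(ev_strict$family_id, "F01")
  # calls invariant to row order
  perm <- d[c(3, 1, 4, 2), ]
  ev2 <- call_shared_strains(perm, meta, threshold = 0.2)
  expect_equal(ev2[order(ev2$family_id), ], ev[order(ev$family_id), ],
               ignore_attr = TRUE)
})

test_that("sharing summary reproduces published cohort totals", {
  tab <- read_sharing_counts(
    system.file("extdata", "dyad_sharing_events_table.tsv",
                package = "dyadshift"))
  events <- expand_sharing_counts(tab)
  events$breastfeeding <- factor(events$breastfeeding)
  summ <- summarize_sharing(events)
  expect_equal(summ$totals$n_strains, 51L)
  expect_equal(summ$totals$n_species, 30L)
  expect_equal(summ$totals$n_genera, 7L)
  expect_equal(summ$table$species[1], "Bacteroides_ovatus")
  expect_equal(max(summ$table$total), 4L)
  # genus-level breakdown
  expect_equal(sum(summ$table$total[genus_of(summ$table$species) ==
                                      "Bacteroides"]), 36L)
  empty <- summarize_sharing(events[0, ])
  expect_equal(empty$totals, list(n_strains = 0L, n_species = 0L,
                                  n_genera = 0L))
})

test_that("neighbor-joining trees solve the three-point formulas", {
  d3 <- matrix(c(0, 0.3, 0.4,
                 0.3, 0, 0.5,
                 0.4, 0.5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- build_nj_tree(d3)
  tree <- ape::read.tree(text = nwk)
  coph <- ape::cophenetic.phylo(tree)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(coph, d3, tolerance = 1e-12)

  # additive 4-taxon matrix: path lengths recover the input exactly
  ref <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.3,d:0.4):0.05);")
  dd <- ape::cophenetic.phylo(ref)
  tree4 <- ape::read.tree(text = build_nj_tree(dd))
  expect_equal(ape::cophenetic.phylo(tree4)[rownames(dd), colnames(dd)],
               dd, tolerance = 1e-12)
  # the newick string reparses to the same tree
  expect_equal(ape::cophenetic.phylo(
    ape::read.tree(text = build_nj_tree(dd)))[rownames(dd), colnames(dd)],
    ape::cophenetic.phylo(tree4)[rownames(dd), colnames(dd)])
  expect_error(build_nj_tree(d3[1:2, 1:2]), ">= 3")
})

test_that("planted transmissions are recovered exactly from haplotypes", {
  co <- generate_cohort(cohort_config(
    n_families = 5, n_species = 5, n_genes_per_species = 20,
    alignment_length = 1000, transmission_probability = 0.5,
    transmitted_strain_divergence = 1e-4,
    background_strain_divergence = 1e-2, n_pathways = 10, seed = 21))
  dists <- do.call(rbind, lapply(co$alignments, pair_distances))
  dists <- normalize_distances(classify_pairs(dists, co$metadata))
  ev <- call_shared_strains(dists, co$metadata)
  expect_setequal(paste(ev$species, ev$family_id),
                  paste(co$truth$transmissions$species,
                        co$truth$transmissions$family_id))
})

test_that("within-family planted pairs sit below the background distances", {
  for (seed in 1:10) {
    co <- generate_cohort(cohort_config(
      n_families = 3, n_species = 3, n_genes_per_species = 5,
      alignment_length = 500, transmission_probability = 0.6,
      n_pathways = 5, seed = seed))
    if (nrow(co$truth$transmissions) == 0) next
    dists <- do.call(rbind, lapply(co$alignments, pair_distances))
    dists <- normalize_distances(classify_pairs(dists, co$metadata))
    planted <- paste(dists$species, dists$family_id) %in%
      paste(co$truth$transmissions$species,
            co$truth$transmissions$family_id) &
      dists$pair_class == "within_family_mother_infant"
    if (!any(planted) || all(planted)) next
    expect_lt(mean(dists$normalized_distance[planted]),
              mean(dists$normalized_distance[!planted]))
  }
})
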