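test_that("cohort config validates its invariants", {
  expect_s3_class(tiny_config(), "cohort_config")
  expect_error(cohort_config(activated_fraction = 1.2), "fractions")
  expect_error(cohort_config(activation_fold = 2), "activation_fold")
  expect_error(cohort_config(background_strain_divergence = 0.8),
               "divergences")
  expect_error(cohort_config(activated_fraction = 0.6,
                             deactivated_fraction = 0.6), "<= 1")
})

test_that("a fixed seed gives byte-identical cohorts", {
  cfg <- tiny_config(seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 5)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("planted truth matches the configured event rates", {
  # no transmissions planted when the probability is zero
  co0 <- generate_cohort(tiny_config(transmission_probability = 0))
  expect_equal(nrow(co0$truth$transmissions), 0)
  expect_equal(nrow(co0$truth$shifts), 0)

  # 10% of 500 genes -> exactly 50 planted activations per transmitted strain
  co <- generate_cohort(cohort_config(
    n_families = 2, n_species = 2, n_genes_per_species = 500,
    transmission_probability = 1, activated_fraction = 0.1,
    deactivated_fraction = 0.1, alignment_length = 200, seed = 3))
  expect_equal(nrow(co$truth$transmissions), 4)
  acts <- co$truth$shifts[co$truth$shifts$direction == "activated", ]
  per_strain <- table(paste(acts$family_id, acts$species))
  expect_true(all(per_strain == 50))
  # every planted shift refers to a planted transmission
  expect_true(all(paste(co$truth$shifts$family_id, co$truth$shifts$species)
                  %in% paste(co$truth$transmissions$family_id,
                             co$truth$transmissions$species)))
})

test_that("generated tables satisfy their container invariants", {
  co <- generate_cohort(tiny_config(seed = 5))
  expect_s3_class(co$dna, "gene_family_table")
  expect_true(all(tapply(co$dna$cpm, co$dna$sample_id, sum) <= 1e6))
  expect_true(all(tapply(co$rna$cpm, co$rna$sample_id, sum) <= 1e6))
  expect_equal(unname(rowSums(co$taxonomic)), rep(1, 6), tolerance = 1e-9)
  expect_true(all(vapply(co$alignments, function(a)
    a$alignment_length == 400, TRUE)))
  # about half the gene ids carry the unannotated suffix
  expect_equal(mean(is_unannotated(unique(co$dna$gene_family))), 0.5,
               tolerance = 0.1)
})

test_that("mutate_haplotype hits sites at the requested divergence", {
  seqA <- paste(rep("A", 20), collapse = "")
  set.seed(1)
  expect_identical(mutate_haplotype(seqA, 0), seqA)
  expect_error(mutate_haplotype(seqA, 0.75), "0.75")
  expect_error(mutate_haplotype(seqA, -0.1), "0.75")
  expect_error(mutate_haplotype("ACGX", 0.1), "ancestor")

  # binomial sampling bound: observed p-distance within 3 binomial sd
  L <- 10000; d <- 0.01
  set.seed(7)
  anc <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  mut <- mutate_haplotype(anc, d)
  p_obs <- p_distance(anc, mut)$p
  expect_lt(abs(p_obs - d), 3 * sqrt(d * (1 - d) / L))
})
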