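test_that("CPM scaling sums to one million", {
  expect_equal(to_cpm(c(1, 1, 2)), c(250000, 250000, 500000))
  expect_equal(to_cpm(5), 1e6)
  expect_equal(to_cpm(c(3, 4), assume_cpm = TRUE), c(3, 4))
  expect_error(to_cpm(c(0, 0)), "zero")
  expect_error(to_cpm(c(-1, 2)), "negative")
})

test_that("relative expression is the median-normalized RNA/DNA ratio", {
  dna <- make_gft(rep("S1", 3), "sp", c("g1", "g2", "g3"), c(10, 10, 10))
  rna <- make_gft(rep("S1", 3), "sp", c("g1", "g2", "g3"), c(10, 20, 40),
                  "RNA")
  rec <- relative_expression(dna, rna, "sp", "S1", min_genes = 3)
  expect_equal(rec$ratio, c(1, 2, 4))
  expect_equal(rec$median_ratio, rep(2, 3))
  expect_equal(rec$relative_expression, c(0.5, 1, 2))

  # all rna = dna -> all relative expression 1
  rec1 <- relative_expression(dna, dna, "sp", "S1", min_genes = 3)
  expect_equal(rec1$relative_expression, rep(1, 3))

  # dna = 0 gene excluded from stratum and median; rna = 0 gives ratio 0
  dna0 <- make_gft(rep("S1", 4), "sp", paste0("g", 1:4), c(10, 10, 10, 0))
  rna0 <- make_gft(rep("S1", 4), "sp", paste0("g", 1:4), c(0, 20, 40, 5),
                   "RNA")
  rec0 <- relative_expression(dna0, rna0, "sp", "S1", min_genes = 3)
  expect_equal(nrow(rec0), 3)
  expect_false("g4" %in% rec0$gene_family)
  expect_equal(rec0$ratio[rec0$gene_family == "g1"], 0)
  expect_equal(rec0$median_ratio[1], 2)  # median of (0, 2, 4)

  # stratum exclusions: too few genes; all-zero RNA median
  expect_message(
    few <- relative_expression(dna, rna, "sp", "S1", min_genes = 10),
    "excluded")
  expect_equal(nrow(few), 0)
  zero_rna <- make_gft(rep("S1", 3), "sp", paste0("g", 1:3), c(0, 0, 0),
                       "RNA")
  expect_warning(
    z <- relative_expression(dna, zero_rna, "sp", "S1", min_genes = 3),
    "median")
  expect_equal(nrow(z), 0)

  # stratum medians of relative expression are 1 for odd counts
  set.seed(9)
  rna_r <- make_gft(rep("S1", 3), "sp", paste0("g", 1:3), runif(3, 1, 50),
                    "RNA")
  rr <- relative_expression(dna, rna_r, "sp", "S1", min_genes = 3)
  expect_equal(median(rr$relative_expression), 1, tolerance = 1e-12)
})

test_that("relative expression absorbs stratum-wide RNA rescaling", {
  set.seed(10)
  genes <- paste0("g", 1:21)
  dna <- make_gft(rep("S1", 21), "sp", genes, runif(21, 1, 100))
  rna <- make_gft(rep("S1", 21), "sp", genes, runif(21, 0, 100), "RNA")
  base <- relative_expression(dna, rna, "sp", "S1")
  scaled <- rna
  scaled$cpm <- scaled$cpm * 3.7
  rescaled <- relative_expression(dna, gene_family_table(scaled, "RNA"),
                                  "sp", "S1")
  expect_equal(rescaled$relative_expression, base$relative_expression,
               tolerance = 1e-12)
})

test_that("shift calls apply strict activation/deactivation thresholds", {
  mot <- make_records(paste0("g", 1:6), c(1, 1, 2, 0.5, 0, 1))
  inf <- make_records(paste0("g", 1:6), c(3, 0.4, 3, 2, 3, 0))
  calls <- call_shifts(inf, mot)
  expect_equal(calls$direction,
               c("activated",    # 3 vs 1: rel 3 > 2, fold 3 > 2
                 "deactivated",  # 0.4 vs 1: rel < 0.5, fold < 0.5
                 "neutral",      # 3 vs 2: fold 1.5 fails
                 "neutral",      # rel exactly 2 fails the strict >
                 "activated",    # mother 0 -> infinite fold
                 "deactivated")) # infant 0 -> fold 0
  expect_equal(calls$fold[5], Inf)
  # genes absent from one side are never called
  inf_extra <- make_records(c(paste0("g", 1:6), "g7"),
                            c(3, 0.4, 3, 2, 3, 0, 100))
  expect_false("g7" %in% call_shifts(inf_extra, mot)$gene_family)
  # activated and deactivated sets are disjoint on random inputs
  set.seed(11)
  for (i in 1:20) {
    m <- make_records(paste0("g", 1:30), rexp(30))
    f <- make_records(paste0("g", 1:30), rexp(30))
    cc <- call_shifts(f, m)
    expect_equal(
      length(intersect(cc$gene_family[cc$direction == "activated"],
                       cc$gene_family[cc$direction == "deactivated"])), 0)
  }
})

test_that("event counting separates occurrences from unique families", {
  calls <- data.frame(
    species = "sp", family_id = c("FX", "FY", "FY"),
    gene_family = c("G", "G", "H"),
    direction = c("activated", "activated", "deactivated"),
    stringsAsFactors = FALSE)
  universe <- data.frame(
    species = "sp", family_id = rep(c("FX", "FY"), each = 2),
    gene_family = rep(c("G", "H"), 2), stringsAsFactors = FALSE)
  res <- count_events(calls, universe)
  expect_equal(res$per_species$activation_events, 2)
  expect_equal(res$per_species$unique_activated_families, 1)
  expect_equal(res$per_species$unique_deactivated_families, 1)
  expect_equal(res$totals$activation_pct, 2 / 4 * 100)
  none <- count_events(calls[0, ], universe)
  expect_equal(none$totals$activation_events, 0)
  expect_error(count_events(calls, universe[0, ]), "universe")
})

test_that("replication rate counts gene families shared by several infants", {
  calls <- data.frame(
    species = "sp",
    family_id = c("FX", "FX", "FX", "FY", "FY"),
    gene_family = c("A", "B", "C", "A", "B"),
    direction = "activated", stringsAsFactors = FALSE)
  expect_equal(replication_rate(calls, "sp"), 2 / 3)
  expect_equal(replication_rate(calls[c(1, 2, 4, 5), ], "sp"), 1)
  expect_true(is.na(replication_rate(calls[1:3, ], "sp")))  # one pair
  expect_true(is.na(replication_rate(calls, "other")))
})

test_that("annotated-rate test matches exact signed-rank enumeration", {
  # six strains; activated gene families always less annotated than the
  # strain-wide 60%, with distinct paired differences
  universe <- do.call(rbind, lapply(1:6, function(i) {
    genes <- sprintf("F%d_g%02d", i, 1:25)
    genes[16:25] <- paste0(genes[16:25], "_unknown")  # 15/25 annotated
    data.frame(species = "sp", family_id = paste0("F", i),
               gene_family = genes, stringsAsFactors = FALSE)
  }))
  calls <- do.call(rbind, lapply(1:6, function(i) {
    genes <- universe$gene_family[universe$family_id == paste0("F", i)]
    annotated <- genes[!is_unannotated(genes)]
    unann <- genes[is_unannotated(genes)]
    act <- c(head(annotated, i - 1), head(unann, 10 - (i - 1)))
    data.frame(species = "sp", family_id = paste0("F", i),
               gene_family = act, direction = "activated",
               stringsAsFactors = FALSE)
  }))
  res <- annotation_rate_test(calls, universe)
  expect_equal(res$per_strain$all_pct, rep(60, 6))
  expect_equal(sort(res$per_strain$activated_pct), seq(0, 50, by = 10))
  # exact two-sided signed-rank p for six strictly negative differences
  expect_equal(res$p_activated, 2 / 64)
  expect_equal(res$p_activated,
               signed_rank_exact_p(res$per_strain$activated_pct -
                                     res$per_strain$all_pct))
  expect_true(is.na(res$p_deactivated))  # no deactivated calls

  # identical percentage pairs -> p = 1
  calls_all <- universe
  calls_all$direction <- "activated"
  expect_equal(annotation_rate_test(calls_all, universe)$p_activated, 1)
})

test_that("eligibility requires a transcriptome signal on both sides", {
  co <- generate_cohort(cohort_config(
    n_families = 3, n_species = 3, n_genes_per_species = 40,
    alignment_length = 500, transmission_probability = 1,
    n_pathways = 5, seed = 31))
  ev <- data.frame(species = "Species_01", family_id = "F01",
                   mother_sample = "M01", infant_sample = "I01",
                   stringsAsFactors = FALSE)
  expect_equal(nrow(detect_shared_transcribed_strains(ev, co$dna, co$rna)),
               1)
  # empty infant RNA stratum -> excluded
  rna_cut <- co$rna[!(co$rna$sample_id == "I01" &
                        co$rna$species == "Species_01"), ]
  rna_cut <- gene_family_table(as.data.frame(rna_cut), "RNA")
  expect_equal(nrow(detect_shared_transcribed_strains(ev, co$dna, rna_cut)),
               0)
  expect_equal(nrow(detect_shared_transcribed_strains(ev[0, ], co$dna,
                                                      co$rna)), 0)
})

test_that("planted expression shifts are recovered exactly at zero noise", {
  co <- generate_cohort(cohort_config(
    n_families = 3, n_species = 3, n_genes_per_species = 50,
    alignment_length = 500, transmission_probability = 1,
    ratio_noise_sd = 0, activation_fold = 4, n_pathways = 5, seed = 41))
  events <- data.frame(
    species = co$truth$transmissions$species,
    family_id = co$truth$transmissions$family_id,
    mother_sample = sub("F", "M", co$truth$transmissions$family_id),
    infant_sample = sub("F", "I", co$truth$transmissions$family_id),
    stringsAsFactors = FALSE)
  res <- shift_analysis(events, co$dna, co$rna, co$metadata)
  called <- res$calls[res$calls$direction != "neutral", ]
  expect_setequal(
    paste(called$species, called$family_id, called$gene_family,
          called$direction),
    paste(co$truth$shifts$species, co$truth$shifts$family_id,
          co$truth$shifts$gene_family, co$truth$shifts$direction))
})

test_that("families with several infant samples are rejected", {
  meta <- make_metadata(2)
  meta <- rbind(meta, data.frame(sample_id = "I99", family_id = "F01",
                                 role = "infant", breastfeeding = "unknown",
                                 site = "NZ"))
  ev <- data.frame(species = "sp", family_id = "F01",
                   mother_sample = "M01", infant_sample = "I01")
  dna <- make_gft("S1", "sp", "g1", 1)
  expect_error(shift_analysis(ev, dna, dna, meta), "multiple infant")
})
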