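test_that("completeness filter applies the >= min_loci rule", {
  gt <- gt_from_strings(list(
    full = rep("1/2", 9),
    seven = c(rep("1/1", 7), NA, NA),
    empty = rep(NA_character_, 9)))
  res <- filter_by_loci_typed(gt, min_loci = 7)
  expect_equal(res$passed$samples$sample_id, c("full", "seven"))
  expect_equal(res$report$n_samples_in, 3)
  expect_equal(res$report$n_passing_filter, 2)
  res1 <- filter_by_loci_typed(gt, min_loci = 1)
  expect_false("empty" %in% res1$passed$samples$sample_id)
  expect_error(filter_by_loci_typed(gt, 10), "cannot exceed")
})

test_that("P_ID formulas match hand values and the brute-force oracle", {
  one <- probability_of_identity(list(c(0.5, 0.5)))
  expect_equal(one$p_id, 0.375)
  expect_equal(one$p_id_sib, 0.59375)
  two <- probability_of_identity(list(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(two$p_id, 0.140625)

  set.seed(17)
  for (k in 2:6) {
    p <- as.numeric(rdirichlet_test(k))
    got <- probability_of_identity(list(p))
    expect_equal(got$p_id, oracle_pid(p), tolerance = 1e-12)
    expect_equal(got$p_id_sib, oracle_pid_sib(p), tolerance = 1e-12)
  }
  expect_error(probability_of_identity(list(c(0.5, 0.6))), "sum to 1")
})

test_that("P_ID strictly decreases as informative loci are added", {
  set.seed(19)
  freqs <- lapply(1:6, function(i) as.numeric(rdirichlet_test(4)))
  vals <- vapply(1:6, function(m) {
    unlist(probability_of_identity(freqs[1:m])[c("p_id", "p_id_sib")])
  }, numeric(2))
  expect_true(all(diff(vals[1, ]) < 0))
  expect_true(all(diff(vals[2, ]) < 0))
})

test_that("genotype matching groups identical genotypes, skips missing loci", {
  gt <- gt_from_strings(list(
    a = rep("1/2", 9),
    b = rep("1/2", 9),
    c = c(rep("1/2", 8), NA),
    d = rep("3/3", 9)))
  m <- match_genotypes(gt, max_mismatch = 0)
  expect_equal(m$n_individuals, 2)
  grp <- m$individual_of
  expect_equal(grp[["a"]], grp[["b"]])
  expect_equal(grp[["a"]], grp[["c"]]) # missing loci are not comparisons
  expect_false(grp[["a"]] == grp[["d"]])
  expect_error(match_genotypes(gt, max_mismatch = 9), "smaller")
})

test_that("matching is symmetric and partitions the sample set", {
  set.seed(23)
  gt <- random_genotype_table(n = 12, L = 6, max_allele = 8, miss = 0.2)
  m <- match_genotypes(gt, max_mismatch = 1)
  expect_setequal(unlist(m$groups), gt$samples$sample_id)
  expect_equal(sum(lengths(m$groups)), n_samples(gt))
})

test_that("consensus calling follows the replicate-support rules", {
  # two identical replicates -> themselves
  r <- gt_from_strings(list(r1 = "1/2", r2 = "1/2"))
  expect_equal(consensus_genotype(r)$genotype[1, ], c(1L, 2L))
  # {AB, AA}: heterozygote wins the two-replicate tie
  r <- gt_from_strings(list(r1 = "1/2", r2 = "1/1"))
  expect_equal(consensus_genotype(r)$genotype[1, ], c(1L, 2L))
  # {AB, AB, AA} -> AB (both alleles confirmed)
  r <- gt_from_strings(list(r1 = "1/2", r2 = "1/2", r3 = "1/1"))
  expect_equal(consensus_genotype(r)$genotype[1, ], c(1L, 2L))
  # {AB, AA, AA}: singleton B demoted with three replicates
  r <- gt_from_strings(list(r1 = "1/2", r2 = "1/1", r3 = "1/1"))
  expect_equal(consensus_genotype(r)$genotype[1, ], c(1L, 1L))
  # conflicting singletons -> missing
  r <- gt_from_strings(list(r1 = "1/1", r2 = "2/2"))
  expect_true(all(is.na(consensus_genotype(r)$genotype[1, ])))
  # single replicate -> itself, low confidence
  r <- gt_from_strings(list(r1 = "3/4"))
  cs <- consensus_genotype(r)
  expect_equal(cs$genotype[1, ], c(3L, 4L))
  expect_true(cs$low_confidence[1])
})

test_that("error rates follow their per-observation definitions", {
  # consensus 1/2 from {1/2, 1/2, 1/1}: dropout 1/3 at that locus
  reps <- gt_from_strings(list(r1 = "1/2", r2 = "1/2", r3 = "1/1"))
  er <- estimate_error_rates(list(reps))
  expect_equal(er$per_locus$dropout[1], 1 / 3)
  expect_equal(er$per_locus$false_allele[1], 0)
  # {1/2, 1/1} with heterozygote-wins consensus 1/2: dropout 1/2
  reps <- gt_from_strings(list(r1 = "1/2", r2 = "1/1"))
  expect_equal(estimate_error_rates(list(reps))$per_locus$dropout[1], 1 / 2)
  # all replicates equal consensus -> both rates 0
  reps <- gt_from_strings(list(r1 = c("1/2", "3/3"), r2 = c("1/2", "3/3")))
  er <- estimate_error_rates(list(reps))
  expect_equal(er$mean_dropout, 0)
  expect_equal(er$mean_false_allele, 0)
  # false allele: replicate contains an allele absent from consensus
  reps <- gt_from_strings(list(r1 = "1/2", r2 = "1/2", r3 = "1/3"))
  er <- estimate_error_rates(list(reps))
  expect_equal(er$per_locus$false_allele[1], 1 / 3)
  # no heterozygous consensus -> dropout NA, not 0
  reps <- gt_from_strings(list(r1 = "1/1", r2 = "1/1"))
  expect_true(is.na(estimate_error_rates(list(reps))$mean_dropout))
})

test_that("error-rate estimators recover generator truth (0.07 dropout, 0 FA)", {
  sim <- simulate_individuals(sim_config(seed = 41))
  wild <- gt_subset(sim$table,
                    samples = which(sim$table$samples$population == "wild"))
  cfg <- sim_config(seed = 41, dropout_rate = 0.07, false_allele_rate = 0,
                    missing_rate = 0, replicates_per_sample = 4,
                    n_field_samples = c(wild = 62))
  reps <- simulate_noninvasive_replicates(wild, cfg)
  groups <- lapply(unique(reps$table$samples$individual_id), function(ind) {
    gt_subset(reps$table,
              samples = which(reps$table$samples$individual_id == ind))
  })
  er <- estimate_error_rates(groups)
  expect_lt(abs(er$mean_dropout - 0.07), 0.02)
  expect_equal(er$mean_false_allele, 0)
})

test_that("zero-noise QC recovers the true individual count (81 -> 62)", {
  sim <- simulate_individuals(sim_config(seed = 51))
  wild <- gt_subset(sim$table,
                    samples = which(sim$table$samples$population == "wild"))
  reps0 <- simulate_noninvasive_replicates(
    wild, sim_config(seed = 51, dropout_rate = 0, false_allele_rate = 0,
                     missing_rate = 0))
  expect_equal(nrow(reps0$field_samples), 81)
  qc <- noninvasive_qc(reps0, min_loci = 7, max_mismatch = 0)
  expect_equal(qc$n_samples_in, 81)
  expect_equal(qc$n_individuals, 62)
  # matched groups coincide with the generator's individual ids
  for (g in qc$match$groups) {
    inds_true <- reps0$field_samples$individual_id[
      match(g, reps0$field_samples$field_sample)]
    expect_equal(length(unique(inds_true)), 1)
  }
})

test_that("study-shaped fixture passes 72 of 81 samples at the 7-locus filter", {
  fx <- make_fixture(seed = 61)
  qc <- noninvasive_qc(fx$replicates, min_loci = 7)
  expect_equal(qc$n_samples_in, 81)
  expect_equal(qc$n_passing_filter, 72)
})
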