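test_that("allele frequencies come from observed gene copies", {
  gt <- gt_from_strings(list(a = "1/1", b = "1/2", c = "2/2"))
  af <- allele_frequencies(gt, 1)
  expect_equal(unname(af$freqs), c(0.5, 0.5))
  expect_equal(af$n_alleles, 2)
  mono <- gt_from_strings(list(a = "3/3", b = "3/3"))
  afm <- allele_frequencies(mono, 1)
  expect_equal(unname(afm$freqs), 1)
  expect_equal(afm$n_alleles, 1)
  missing_gt <- gt_from_strings(list(a = NA_character_))
  expect_error(allele_frequencies(missing_gt, 1), "no typed")
})

test_that("heterozygosities match hand-computed unbiased values", {
  gt <- gt_from_strings(list(a = "1/1", b = "1/2", c = "2/2"))
  hz <- heterozygosities(gt, 1)
  expect_equal(hz$h_obs, 1 / 3)
  expect_equal(hz$h_exp, (6 / 5) * 0.5) # = 0.6
  expect_equal(fis(hz$h_exp, hz$h_obs), 1 - (1 / 3) / 0.6, tolerance = 1e-12)
  allsame <- gt_from_strings(list(a = "1/1", b = "1/1"))
  hz0 <- heterozygosities(allsame, 1)
  expect_equal(hz0$h_obs, 0)
  expect_equal(hz0$h_exp, 0)
  expect_true(is.na(fis(hz0$h_exp, hz0$h_obs)))
  expect_equal(fis(0.5, 0.5), 0)
  expect_lt(fis(0.5, 0.7), 0) # heterozygote excess is negative
})

test_that("unbiased H_E exceeds the plug-in gene diversity in finite samples", {
  set.seed(29)
  sim <- simulate_individuals(sim_config(seed = 29))
  for (l in seq_len(3)) {
    af <- allele_frequencies(sim$table, l)
    hz <- heterozygosities(sim$table, l)
    expect_gt(hz$h_exp, 1 - sum(af$freqs^2))
  }
})

test_that("simulated HWE population has H_O close to H_E near 0.5", {
  cfg <- sim_config(n_loci = 1, alleles_per_locus = 2,
                    z_linked_loci = integer(), n_clusters = 1,
                    drift_f = 0.001,
                    pop_sizes = matrix(2000, 1, 1, dimnames = list("p", NULL)),
                    sex_ratio = c(p = 0.5), hybrid_frac = 0,
                    n_field_samples = integer(), seed = 77)
  sim <- simulate_individuals(cfg)
  hz <- heterozygosities(sim$table, 1)
  p <- sim$truth$cluster_freqs[[1]][[1]][1]
  expect_lt(abs(hz$h_obs - 2 * p * (1 - p)), 0.03)
  expect_lt(abs(hz$h_exp - hz$h_obs), 0.03)
})

test_that("HWE exact test reproduces the two-table hand enumeration", {
  ct <- as_genotype_counts(c("1/1" = 1, "2/2" = 1))
  res <- hwe_exact_test(ct)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "enumeration")
  expect_equal(res$n_tables, 2)
  mono <- as_genotype_counts(c("1/1" = 10))
  expect_equal(hwe_exact_test(mono)$p_value, 1)
  expect_equal(hwe_exact_test(mono)$method, "monomorphic")
})

test_that("HWE enumeration equals the random-pairing oracle on small tables", {
  set.seed(37)
  cases <- list(
    c("1/1" = 2, "1/2" = 1, "2/2" = 2),
    c("1/2" = 4),
    c("1/1" = 1, "2/2" = 1, "3/3" = 1),
    c("1/1" = 2, "1/2" = 2, "2/3" = 1, "3/3" = 1),
    c("1/2" = 2, "1/3" = 2, "2/3" = 2),
    c("1/1" = 3, "1/2" = 1, "2/2" = 2, "1/3" = 1, "3/3" = 1))
  for (cs in cases) {
    got <- hwe_exact_test(as_genotype_counts(cs))
    expect_equal(got$method, "enumeration")
    expect_equal(got$p_value, oracle_hwe_p(cs), tolerance = 1e-12,
                 label = paste(names(cs), cs, collapse = " "))
  }
})

test_that("Monte-Carlo HWE mode converges to the enumerated p-value", {
  cs <- c("1/1" = 4, "1/2" = 2, "2/2" = 6)
  ct <- as_genotype_counts(cs)
  exact <- hwe_exact_test(ct)$p_value
  mc <- hwe_exact_test(ct, enumeration_bound = 1, n_sim = 2e4, seed = 5)
  expect_equal(mc$method, "monte_carlo")
  se <- sqrt(exact * (1 - exact) / 2e4)
  expect_lt(abs(mc$p_value - exact), 3 * se + 1e-4)
})

test_that("the exact test holds its size on simulated HWE loci", {
  # biallelic HWE genotypes at n = 50; rejection rate at alpha = .05 must
  # not exceed it (exact-test conservatism)
  set.seed(43)
  n_rej <- 0
  n_loci_sim <- 400
  for (i in seq_len(n_loci_sim)) {
    p <- runif(1, 0.2, 0.8)
    g <- sample(1:3, 50, replace = TRUE,
                prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
    cs <- c("1/1" = sum(g == 1), "1/2" = sum(g == 2), "2/2" = sum(g == 3))
    cs <- cs[cs > 0]
    pv <- hwe_exact_test(as_genotype_counts(cs))$p_value
    if (pv <= 0.05) n_rej <- n_rej + 1
  }
  expect_lte(n_rej / n_loci_sim, 0.05 + 2 * sqrt(0.05 * 0.95 / n_loci_sim))
})

test_that("BH flags match hand thresholds and the reference step-up", {
  expect_equal(fdr_correct(c(0.001, 0.02, 0.03, 0.2), q = 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_correct(rep(1, 5)), rep(FALSE, 5))
  expect_true(fdr_correct(0.04, q = 0.05))
  expect_equal(fdr_correct(numeric(0)), logical(0))
  set.seed(47)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_equal(fdr_correct(p, q), oracle_bh_flags(p, q))
  }
})

test_that("null-allele ML is near zero without homozygote excess", {
  set.seed(53)
  p <- c(0.4, 0.35, 0.25)
  g <- replicate(500, sort(sample(1:3, 2, replace = TRUE, prob = p)))
  cs <- table(paste0(g[1, ], "/", g[2, ]))
  fit <- null_allele_ml(as_genotype_counts(setNames(as.integer(cs), names(cs))))
  expect_lt(fit$naf, 0.02)
})

test_that("null-allele ML recovers a planted r = 0.30 with scored blanks", {
  set.seed(59)
  p_vis <- c(0.3, 0.25, 0.15)  # plus null at 0.30
  r <- 0.30
  probs <- c(p_vis, r)
  g <- replicate(500, sample(1:4, 2, replace = TRUE, prob = probs))
  obs <- apply(g, 2, function(x) {
    if (all(x == 4)) return(NA_character_)          # blank
    x[x == 4] <- x[x != 4][1]                       # null het looks homozygous
    paste(sort(x), collapse = "/")
  })
  blanks <- sum(is.na(obs))
  cs <- table(obs[!is.na(obs)])
  fit <- null_allele_ml(as_genotype_counts(setNames(as.integer(cs), names(cs))),
                        n_blank = blanks, beta = 0)
  expect_lt(abs(fit$naf - 0.30), 0.05)
  # the beta-estimating default should land close as well here
  fit2 <- null_allele_ml(as_genotype_counts(setNames(as.integer(cs), names(cs))),
                         n_blank = blanks)
  expect_lt(abs(fit2$naf - 0.30), 0.07)
})

test_that("null-allele ML edge cases and monotone response", {
  allhet <- as_genotype_counts(c("1/2" = 30, "1/3" = 20, "2/3" = 25))
  expect_lt(null_allele_ml(allhet)$naf, 1e-6)
  # inflating homozygote counts never decreases r-hat
  base <- c("1/1" = 10, "1/2" = 30, "2/2" = 10)
  prev <- -1
  for (extra in c(0, 10, 25, 50)) {
    cs <- base; cs["1/1"] <- cs["1/1"] + extra
    fit <- null_allele_ml(as_genotype_counts(cs))
    expect_gte(fit$naf, prev - 1e-9)
    prev <- fit$naf
  }
  expect_error(null_allele_ml(as_genotype_counts(integer(0))))
})

test_that("population summary assembles per-locus rows and both averages", {
  set.seed(61)
  gt <- random_genotype_table(n = 25, L = 4, max_allele = 5, miss = 0)
  s <- summarize_population(gt, exclude_loci = c("L1", "L2"))
  expect_equal(nrow(s$per_locus), 4)
  expect_equal(s$average$h_exp, mean(s$per_locus$h_exp))
  expect_equal(s$average_excluding$h_exp, mean(s$per_locus$h_exp[3:4]))
  s0 <- summarize_population(gt)
  expect_equal(s0$average, s0$average_excluding)
  expect_error(summarize_population(gt, exclude_loci = "nope"), "subset")
})
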