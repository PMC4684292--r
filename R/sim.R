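#' Simulation configuration for the two-lineage, two-population design
#'
#' Builds the configuration object for the synthetic-data generator. The
#' defaults emulate the study design the pipeline is meant for: a captive
#' breeding flock of 42 birds (17 wild-born founders from two lineages plus
#' 25 flock-born offspring, male:female ratio 1:2.2) and a reintroduced
#' population of 62 individuals detected through 81 faecal samples; nine
#' microsatellite-like loci of which the first two are Z-linked; three
#' genetic clusters (the "Belarusian" lineage plus an internally
#' substructured "Western Carpathian" lineage) diverged by drift from a
#' common ancestral frequency set; and a shared/unique mtDNA haplotype pool.
#'
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus integer vector (recycled) of allele-alphabet
#'   sizes per locus.
#' @param z_linked_loci integer indices of Z-linked loci (possibly empty).
#'   Males are ZZ (diploid); females are ZW and carry a single Z allele,
#'   which the generator *records* as a homozygous diploid call, mirroring
#'   how fragment analysis scores hemizygotes.
#' @param n_clusters number of genetic clusters.
#' @param drift_f per-cluster drift parameter in (0,1) (recycled); the
#'   F-model divergence of each cluster from the ancestral frequencies.
#' @param pop_sizes matrix `populations x clusters` of individual counts;
#'   rownames are population names.
#' @param sex_ratio named numeric vector of *male proportions* per
#'   population. The captive default 1/3.2 encodes the 1:2.2 male:female
#'   ratio; the wild ratio is unknown in the field and defaults to 0.5.
#' @param hybrid_frac fraction of each population converted into 50/50
#'   first-generation admixed individuals between two random clusters
#'   (scalar, or named per population).
#' @param mtdna_pool matrix `populations x haplotype labels` of haplotype
#'   frequencies (rows sum to 1).
#' @param dropout_rate per-genotype probability that a true heterozygote
#'   loses one allele in a faecal replicate (apparent homozygote).
#' @param false_allele_rate per-allele probability that a surviving allele
#'   is replaced by a random other allele of the locus alphabet.
#' @param missing_rate per-locus probability that a replicate call fails
#'   entirely.
#' @param replicates_per_sample PCR replicates per faecal sample (the field
#'   standard of genotyping every non-invasive sample at least twice).
#' @param n_field_samples named integer vector: faecal samples collected per
#'   population (only populations listed here are faecal-sampled).
#' @param seed integer seed; all generator randomness derives from it
#'   through a fixed substream scheme (see Details).
#'
#' @details Randomness is organised in hierarchical substreams: each
#' generator component seeds R's RNG with `seed + 1000003 * k` (mod
#' 2^31 - 19) for a fixed component index `k`, so adding a component (e.g.
#' one more population's replicates) does not perturb draws made by earlier
#' components.
#'
#' @return a validated `sim_config` object (list).
#' @export
sim_config <- function(n_loci = 9,
                       alleles_per_locus = c(4, 5, 5, 5, 8, 7, 6, 7, 6),
                       z_linked_loci = c(1, 2),
                       n_clusters = 3,
                       drift_f = 0.15,
                       pop_sizes = rbind(captive = c(15, 10, 17),
                                         wild = c(15, 30, 17)),
                       sex_ratio = c(captive = 1 / 3.2, wild = 0.5),
                       hybrid_frac = c(captive = 0.12, wild = 0.16),
                       mtdna_pool = default_mtdna_pool(),
                       dropout_rate = 0.07,
                       false_allele_rate = 0,
                       missing_rate = 0.1,
                       replicates_per_sample = 2,
                       n_field_samples = c(wild = 81),
                       seed = 1) {
  alleles_per_locus <- as.integer(rep_len(alleles_per_locus, n_loci))
  drift_f <- rep_len(drift_f, n_clusters)
  cfg <- list(n_loci = as.integer(n_loci),
              alleles_per_locus = alleles_per_locus,
              z_linked_loci = as.integer(z_linked_loci),
              n_clusters = as.integer(n_clusters),
              drift_f = drift_f,
              pop_sizes = pop_sizes,
              sex_ratio = sex_ratio,
              hybrid_frac = hybrid_frac,
              mtdna_pool = mtdna_pool,
              dropout_rate = dropout_rate,
              false_allele_rate = false_allele_rate,
              missing_rate = missing_rate,
              replicates_per_sample = as.integer(replicates_per_sample),
              n_field_samples = n_field_samples,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_loci < 1) stop("n_loci must be >= 1")
    if (any(alleles_per_locus < 1)) stop("alleles_per_locus must be >= 1")
    if (length(z_linked_loci) && (any(z_linked_loci < 1) ||
                                  any(z_linked_loci > n_loci))) {
      stop("z_linked_loci must be a subset of 1..n_loci")
    }
    if (any(drift_f <= 0 | drift_f >= 1)) stop("drift_f must lie in (0,1)")
    if (!is.matrix(pop_sizes) || ncol(pop_sizes) != n_clusters) {
      stop("pop_sizes must be a populations x clusters matrix")
    }
    if (is.null(rownames(pop_sizes))) stop("pop_sizes needs population rownames")
    if (any(pop_sizes < 0)) stop("pop_sizes must be non-negative")
    if (any(rowSums(pop_sizes) == 0)) stop("empty population in pop_sizes")
    probs <- c(dropout_rate, false_allele_rate, missing_rate, hybrid_frac,
               sex_ratio)
    if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0,1]")
    if (!all(rownames(pop_sizes) %in% names(sex_ratio))) {
      stop("sex_ratio must name every population")
    }
    if (!is.matrix(mtdna_pool) || is.null(colnames(mtdna_pool))) {
      stop("mtdna_pool must be a populations x haplotypes frequency matrix")
    }
    if (any(abs(rowSums(mtdna_pool) - 1) > 1e-9)) {
      stop("mtdna_pool rows must sum to 1")
    }
    if (replicates_per_sample < 1) stop("replicates_per_sample must be >= 1")
  })
  invisible(cfg)
}

#' Default mtDNA haplotype pool: nine haplotypes, four shared
#'
#' Frequencies chosen so that the captive pool spans seven haplotypes
#' (H1-H7) and the wild pool six (H2, H4, H6, H7, H8, H9): four shared,
#' three unique to the captive population and two to the wild one.
#' @return populations x haplotypes frequency matrix.
#' @export
default_mtdna_pool <- function() {
  haps <- paste0("H", 1:9)
  pool <- rbind(
    captive = c(0.12, 0.35, 0.09, 0.17, 0.09, 0.09, 0.09, 0, 0),
    wild    = c(0, 11 / 62, 0, 27 / 62, 0, 2 / 62, 1 / 62, 20 / 62, 1 / 62))
  colnames(pool) <- haps
  pool
}

# substream scheme: component k of a run with global seed s
sim_substream <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483629)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) { # numerically degenerate very small alphas
    out <- numeric(length(alpha)); out[which.max(alpha)] <- 1
    return(out)
  }
  g / sum(g)
}

#' Drift-diverge cluster allele frequencies from an ancestral set
#'
#' Draws per-cluster, per-locus allele frequencies from the F-model: each
#' cluster's frequency vector is Dirichlet with mean equal to the ancestral
#' vector and concentration `(1 - F) / F`, so clusters drift apart more the
#' larger `F`.
#'
#' @param ancestral list of per-locus allele-frequency vectors (each sums
#'   to 1).
#' @param drift_f numeric vector of per-cluster divergence in (0,1); its
#'   length sets the number of clusters.
#' @param seed optional integer seed.
#' @return list (clusters) of lists (loci) of frequency vectors.
#' @export
simulate_cluster_frequencies <- function(ancestral, drift_f, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(ancestral, function(p) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("ancestral vectors must be probability vectors summing to 1")
    }
  })
  if (any(drift_f <= 0 | drift_f >= 1)) stop("drift_f must lie in (0,1)")
  lapply(drift_f, function(f) {
    conc <- (1 - f) / f
    lapply(ancestral, function(p) {
      q <- rdirichlet1(p * conc)
      q / sum(q)
    })
  })
}

#' Simulate the individuals of all populations with full ground truth
#'
#' Draws ancestral allele frequencies (flat Dirichlet over each locus
#' alphabet), drift-diverges them into clusters, assigns cluster
#' memberships, sexes and mtDNA haplotypes, and draws every genotype.
#' Autosomal gene copies are drawn independently, each from a cluster
#' chosen by the individual's membership proportions (admixed individuals
#' therefore mix within a genotype, matching the admixture clustering
#' model's own assumption). At Z-linked loci males (ZZ) receive two alleles
#' and females (ZW) one, recorded as a homozygous diploid call.
#'
#' @param config a [sim_config()].
#' @return list with `truth` (class `population_truth`: `ancestral_freqs`,
#'   `cluster_freqs`, `memberships` matrix, `sexes`, `mtdna`, `hemizygous`
#'   logical matrix, `true_calls` array) and `table` (the recorded
#'   [genotype_table()]).
#' @export
simulate_individuals <- function(config) {
  validate_sim_config(config)
  L <- config$n_loci
  pops <- rownames(config$pop_sizes)
  n_by_pop <- rowSums(config$pop_sizes)
  n <- sum(n_by_pop)
  if (n == 0) stop("no individuals to simulate")
  K <- config$n_clusters

  set.seed(sim_substream(config$seed, 1))
  ancestral <- lapply(config$alleles_per_locus, function(a) rdirichlet1(rep(1, a)))
  cluster_freqs <- simulate_cluster_frequencies(ancestral, config$drift_f)

  # memberships, sexes, haplotypes (component 2)
  set.seed(sim_substream(config$seed, 2))
  pop_of <- rep(pops, n_by_pop)
  Q <- matrix(0, n, K)
  idx <- 0L
  for (p in pops) {
    for (k in seq_len(K)) {
      cnt <- config$pop_sizes[p, k]
      if (cnt > 0) Q[idx + seq_len(cnt), k] <- 1
      idx <- idx + cnt
    }
  }
  # convert a fraction of each population into 50/50 hybrids
  for (p in pops) {
    rows <- which(pop_of == p)
    hf <- if (!is.null(names(config$hybrid_frac)))
            config$hybrid_frac[[p]] else config$hybrid_frac[1]
    n_h <- round(hf * length(rows))
    if (n_h > 0 && K >= 2) {
      hy <- sample(rows, n_h)
      for (i in hy) {
        pair <- sample.int(K, 2)
        Q[i, ] <- 0; Q[i, pair] <- 0.5
      }
    }
  }
  sexes <- character(n)
  for (p in pops) {
    rows <- which(pop_of == p)
    n_m <- round(config$sex_ratio[[p]] * length(rows))
    sx <- rep("female", length(rows)); sx[seq_len(n_m)] <- "male"
    sexes[rows] <- sample(sx)
  }
  haps <- character(n)
  for (p in pops) {
    rows <- which(pop_of == p)
    pool <- if (p %in% rownames(config$mtdna_pool)) {
      config$mtdna_pool[p, ]
    } else { # population without a dedicated pool: uniform over labels
      rep(1 / ncol(config$mtdna_pool), ncol(config$mtdna_pool))
    }
    haps[rows] <- sample(colnames(config$mtdna_pool), length(rows),
                         replace = TRUE, prob = pool)
  }

  # genotypes (component 3)
  set.seed(sim_substream(config$seed, 3))
  true_calls <- array(NA_integer_, dim = c(n, L, 2))
  hemi <- matrix(FALSE, n, L)
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      z_locus <- l %in% config$z_linked_loci
      copies <- if (z_locus && sexes[i] == "female") 1L else 2L
      ks <- sample.int(K, copies, replace = TRUE, prob = Q[i, ])
      al <- vapply(ks, function(k) {
        sample.int(config$alleles_per_locus[l], 1,
                   prob = cluster_freqs[[k]][[l]])
      }, integer(1))
      if (copies == 1L) {
        true_calls[i, l, ] <- c(al, NA_integer_)
        hemi[i, l] <- TRUE
      } else {
        true_calls[i, l, ] <- sort(al)
      }
    }
  }
  recorded <- true_calls
  # hemizygous single alleles are recorded as homozygous diploid calls
  one <- is.na(recorded[, , 2]) & !is.na(recorded[, , 1])
  recorded[, , 2][one] <- recorded[, , 1][one]

  ids <- sprintf("%s_%03d", pop_of, stats::ave(seq_len(n), pop_of, FUN = seq_along))
  samples <- data.frame(sample_id = ids, individual_id = ids,
                        population = pop_of,
                        lineage_prior = NA_character_,
                        sex = sexes, locality = pop_of, source = "blood",
                        stringsAsFactors = FALSE)
  table <- genotype_table(samples, paste0("loc", seq_len(L)), recorded)
  rownames(Q) <- ids
  truth <- structure(list(ancestral_freqs = ancestral,
                          cluster_freqs = cluster_freqs,
                          memberships = Q, sexes = stats::setNames(sexes, ids),
                          mtdna = stats::setNames(haps, ids),
                          hemizygous = hemi, true_calls = true_calls,
                          population = stats::setNames(pop_of, ids)),
                     class = "population_truth")
  list(truth = truth, table = table)
}

#' Simulate replicated non-invasive (faecal) genotypings
#'
#' Turns a table of true individual genotypes into a set of faecal field
#' samples with replicated, error-prone genotypes. Redundant field samples
#' of the same individual share its true genotype. Per replicate and locus:
#' a true heterozygote loses one allele with probability `dropout_rate`
#' (apparent homozygote); each surviving allele is then replaced by a random
#' *other* allele of the locus alphabet with probability
#' `false_allele_rate`; finally the whole locus call is set missing with
#' probability `missing_rate`.
#'
#' @param table a [genotype_table()] of true genotypes (one row per
#'   individual) for the faecal-sampled population(s).
#' @param config a [sim_config()]; `n_field_samples` entries matching the
#'   table's populations determine how many field samples are drawn (each
#'   individual is sampled at least once, extras are drawn uniformly).
#' @return a `replicate_set`: list with `table` (one row per replicate;
#'   metadata columns `field_sample`, `replicate`, `individual_id`) and
#'   `field_samples` (data.frame mapping field samples to individuals).
#' @export
simulate_noninvasive_replicates <- function(table, config) {
  validate_sim_config(config)
  set.seed(sim_substream(config$seed, 5))
  pops <- unique(table$samples$population)
  rows_all <- integer(); fs_ids <- character()
  for (p in pops) {
    rows <- which(table$samples$population == p)
    n_fs <- config$n_field_samples[[p]]
    if (is.null(n_fs) || is.na(n_fs)) n_fs <- length(rows)
    if (n_fs < length(rows)) {
      rows_pick <- sample(rows, n_fs)
    } else {
      rows_pick <- c(rows, sample(rows, n_fs - length(rows), replace = TRUE))
    }
    rows_pick <- sample(rows_pick)  # shuffle collection order
    rows_all <- c(rows_all, rows_pick)
    fs_ids <- c(fs_ids, sprintf("%s_S%03d", p, seq_along(rows_pick)))
  }
  R <- config$replicates_per_sample
  n_rep <- length(rows_all) * R
  L <- n_loci(table)
  calls <- array(NA_integer_, dim = c(n_rep, L, 2))
  meta <- data.frame(sample_id = character(n_rep), field_sample = character(n_rep),
                     replicate = integer(n_rep), individual_id = character(n_rep),
                     population = character(n_rep), locality = character(n_rep),
                     sex = character(n_rep), source = "faeces",
                     stringsAsFactors = FALSE)
  at <- 0L
  for (s in seq_along(rows_all)) {
    i <- rows_all[s]
    for (r in seq_len(R)) {
      at <- at + 1L
      calls[at, , ] <- noisy_replicate(table$calls[i, , , drop = TRUE],
                                       config$alleles_per_locus,
                                       config$dropout_rate,
                                       config$false_allele_rate,
                                       config$missing_rate)
      meta$sample_id[at] <- sprintf("%s_r%d", fs_ids[s], r)
      meta$field_sample[at] <- fs_ids[s]
      meta$replicate[at] <- r
      meta$individual_id[at] <- table$samples$individual_id[i]
      meta$population[at] <- table$samples$population[i]
      meta$locality[at] <- table$samples$locality[i]
      meta$sex[at] <- table$samples$sex[i]
    }
  }
  rep_table <- genotype_table(meta, table$loci, calls)
  field_samples <- unique(data.frame(
    field_sample = meta$field_sample, individual_id = meta$individual_id,
    population = meta$population, locality = meta$locality,
    stringsAsFactors = FALSE))
  structure(list(table = rep_table, field_samples = field_samples),
            class = "replicate_set")
}

# one noisy replicate of a true L x 2 call matrix
noisy_replicate <- function(true_call, alleles_per_locus, dropout_rate,
                            false_allele_rate, missing_rate) {
  L <- nrow(true_call)
  out <- true_call
  for (l in seq_len(L)) {
    pr <- out[l, ]
    if (anyNA(pr)) next
    if (pr[1] != pr[2] && stats::runif(1) < dropout_rate) {
      keep <- pr[sample.int(2, 1)]
      pr <- c(keep, keep)
    }
    if (false_allele_rate > 0 && alleles_per_locus[l] > 1) {
      for (c2 in 1:2) {
        if (stats::runif(1) < false_allele_rate) {
          others <- setdiff(seq_len(alleles_per_locus[l]), pr[c2])
          pr[c2] <- if (length(others) == 1) others else sample(others, 1)
        }
      }
    }
    if (stats::runif(1) < missing_rate) pr <- c(NA_integer_, NA_integer_)
    out[l, ] <- sort(pr, na.last = TRUE)
    if (anyNA(out[l, ])) out[l, ] <- NA_integer_
  }
  out
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("replicate_set: %d field samples, %d replicate genotypings, %d loci\n",
              nrow(x$field_samples), n_samples(x$table), n_loci(x$table)))
  invisible(x)
}

#' Write the generator's ground truth as a delimited file
#'
#' One row per individual: population, sex, mtDNA haplotype and cluster
#' membership proportions — the oracle downstream tests recover parameters
#' against.
#'
#' @param truth a `population_truth`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth_table <- function(truth, path) {
  Q <- truth$memberships
  df <- data.frame(individual_id = names(truth$sexes),
                   population = truth$population,
                   sex = truth$sexes, mtdna = truth$mtdna,
                   stringsAsFactors = FALSE)
  colnames(Q) <- paste0("q", seq_len(ncol(Q)))
  utils::write.table(cbind(df, Q), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
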