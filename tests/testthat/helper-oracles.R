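# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own formulas/algorithms.

# P_ID by brute force: sum over all unordered genotypes of (HWE genotype
# probability)^2
oracle_pid <- function(p) {
  k <- length(p)
  tot <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      gp <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      tot <- tot + gp^2
    }
  }
  tot
}

# P_ID(sib) by brute force: P(two full sibs share genotype) under HWE
# parents. Enumerate parental genotype pairs and offspring segregation.
oracle_pid_sib <- function(p) {
  k <- length(p)
  geno <- list()
  for (i in seq_len(k)) for (j in i:k) geno[[length(geno) + 1]] <- c(i, j)
  gprob <- vapply(geno, function(g) {
    if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]]
  }, numeric(1))
  tot <- 0
  for (m in seq_along(geno)) {
    for (f in seq_along(geno)) {
      # offspring genotype distribution from this parent pair
      off <- table(vapply(1:4, function(x) {
        a <- geno[[m]][(x - 1) %/% 2 + 1]
        b <- geno[[f]][(x - 1) %% 2 + 1]
        paste(sort(c(a, b)), collapse = "/")
      }, character(1))) / 4
      tot <- tot + gprob[m] * gprob[f] * sum(off^2)
    }
  }
  tot
}

# Exact null distribution of genotype tables by random pairing of gene
# copies: recursion over the multiset of remaining copies. Returns the
# p-value for the observed genotype count vector (named "i/j").
oracle_hwe_p <- function(obs_counts) {
  prs <- strsplit(names(obs_counts), "/", fixed = TRUE)
  alleles <- sort(unique(as.integer(unlist(prs))))
  m <- setNames(rep(0L, length(alleles)), alleles)
  for (t in seq_along(obs_counts)) {
    pr <- as.integer(prs[[t]])
    m[as.character(pr[1])] <- m[as.character(pr[1])] + obs_counts[t]
    m[as.character(pr[2])] <- m[as.character(pr[2])] + obs_counts[t]
  }
  dist <- new.env()
  rec <- function(rem, acc, prob) {
    if (sum(rem) == 0) {
      key <- paste(sort(acc), collapse = ";")
      dist[[key]] <- (if (is.null(dist[[key]])) 0 else dist[[key]]) + prob
      return(invisible())
    }
    i <- which(rem > 0)[1]
    rem2 <- rem; rem2[i] <- rem2[i] - 1L
    tot <- sum(rem2)
    for (j in which(rem2 > 0)) {
      pr_j <- rem2[j] / tot
      rem3 <- rem2; rem3[j] <- rem3[j] - 1L
      g <- paste(sort(c(alleles[i], alleles[j])), collapse = "/")
      rec(rem3, c(acc, g), prob * pr_j)
    }
  }
  rec(m, character(), 1)
  keys <- ls(dist)
  probs <- vapply(keys, function(k) dist[[k]], numeric(1))
  obs_key <- paste(sort(rep(names(obs_counts), obs_counts)), collapse = ";")
  p_obs <- probs[[obs_key]]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh_flags <- function(p, q) {
  n <- length(p)
  o <- order(p)
  thr <- q * seq_len(n) / n
  passed <- which(p[o] <= thr)
  flags <- logical(n)
  if (length(passed)) flags[o[seq_len(max(passed))]] <- TRUE
  flags
}

# Weir & Cockerham (1984) theta for two or more populations, textbook form
oracle_wc_fst <- function(table) {
  pops <- unique(table$samples$population)
  r <- length(pops)
  num <- den <- 0
  for (l in seq_len(n_loci(table))) {
    by_pop <- lapply(pops, function(p) {
      sub <- gt_subset(table, samples = which(table$samples$population == p))
      a <- sub$calls[, l, 1]; b <- sub$calls[, l, 2]
      ok <- !is.na(a)
      list(n = sum(ok), copies = c(a[ok], b[ok]),
           het = mean(a[ok] != b[ok]))
    })
    alleles <- sort(unique(unlist(lapply(by_pop, `[[`, "copies"))))
    ns <- vapply(by_pop, `[[`, numeric(1), "n")
    nbar <- mean(ns)
    nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      ps <- vapply(by_pop, function(x) mean(x$copies == al), numeric(1))
      # observed frequency of heterozygotes involving allele al, per pop
      hs <- vapply(seq_along(pops), function(pi) {
        p <- pops[pi]
        sub <- gt_subset(table, samples = which(table$samples$population == p))
        a <- sub$calls[, l, 1]; b <- sub$calls[, l, 2]
        ok <- !is.na(a)
        mean((a[ok] != b[ok]) & (a[ok] == al | b[ok] == al))
      }, numeric(1))
      pbar <- sum(ns * ps) / (r * nbar)
      s2 <- sum(ns * (ps - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ns * hs) / (r * nbar)
      a_ <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                 hbar / 4) / (nbar - 1))
      b_ <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                   (2 * nbar - 1) / (4 * nbar) * hbar)
      c_ <- hbar / 2
      num <- num + a_
      den <- den + a_ + b_ + c_
    }
  }
  num / den
}

# random genotype table generator for round-trip property tests
random_genotype_table <- function(n = 8, L = 4, max_allele = 150,
                                  miss = 0.1, pops = c("A", "B")) {
  calls <- array(NA_integer_, dim = c(n, L, 2))
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      if (runif(1) > miss) calls[i, l, ] <- sample(max_allele, 2, replace = TRUE)
    }
  }
  genotype_table(
    data.frame(sample_id = sprintf("s%02d", seq_len(n)),
               # grouped: the Genepop writer emits one block per population
               population = sort(sample(pops, n, replace = TRUE))),
    paste0("L", seq_len(L)), calls)
}

# build a genotype_table from a compact list of "a/b" strings per sample
gt_from_strings <- function(rows, loci = NULL, ...) {
  n <- length(rows)
  L <- length(rows[[1]])
  calls <- array(NA_integer_, dim = c(n, L, 2))
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      s <- rows[[i]][l]
      if (!is.na(s)) calls[i, l, ] <- as.integer(strsplit(s, "/")[[1]])
    }
  }
  meta <- data.frame(sample_id = if (is.null(names(rows)))
                       sprintf("s%02d", seq_len(n)) else names(rows), ...)
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  genotype_table(meta, loci, calls)
}

rdirichlet_test <- function(k, alpha = 1) {
  g <- rgamma(k, alpha)
  g / sum(g)
}
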