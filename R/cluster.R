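#' Gibbs sampler for admixture-model clustering
#'
#' Bayesian clustering of multilocus genotypes under the admixture model:
#' each individual's genome is a mixture over `K` clusters (membership
#' vector `Q`), each cluster carrying its own per-locus allele frequencies
#' (`P`, uncorrelated across clusters). Latent gene-copy origins, `P` and
#' `Q` are Gibbs-updated from their conjugate conditionals; `Q` and `P`
#' are returned as post-burn-in means. Deterministic under a fixed seed.
#'
#' @param table a [genotype_table()]; missing calls are skipped.
#' @param K number of clusters (>= 1).
#' @param alpha Dirichlet prior parameter on memberships (fixed, no
#'   updating).
#' @param burn_in,iterations burn-in sweeps and retained sweeps. The
#'   desk-scale defaults (2000 + 8000) replace the production-scale chains
#'   (hundreds of thousands of sweeps) that full studies run; both are
#'   plain parameters.
#' @param seed integer seed (drives R's RNG, which the sampler uses).
#' @param lambda Dirichlet prior parameter on cluster allele frequencies.
#' @return a `cluster_run`: list with `K`, `Q` (individuals x K posterior
#'   mean, rows sum to 1), `P` (per-cluster per-locus frequency vectors),
#'   `loglik_trace`, `final` (last state incl. gene-copy origins `Z` and
#'   the complete-data log-likelihood, for diagnostics), `seed`,
#'   `burn_in`, `iterations`.
#' @export
gibbs_admixture <- function(table, K, alpha = 1, burn_in = 2000,
                            iterations = 8000, seed = NULL, lambda = 1) {
  stopifnot(inherits(table, "genotype_table"))
  if (K < 1) stop("K must be >= 1")
  if (n_samples(table) == 0) stop("empty genotype table")
  typed <- loci_typed(table)
  if (any(typed == 0)) stop("every individual needs at least one typed locus")
  enc <- encode_alleles(table)
  if (!is.null(seed)) set.seed(seed)
  res <- .gibbs_admixture_cpp(enc$geno, enc$n_alleles, as.integer(K),
                              alpha, lambda, as.integer(burn_in),
                              as.integer(iterations))
  Q <- res$Q
  rownames(Q) <- table$samples$sample_id
  colnames(Q) <- paste0("cluster", seq_len(K))
  structure(list(K = as.integer(K), Q = Q, P = res$P,
                 loglik_trace = as.numeric(res$trace),
                 final = list(Q = res$Q_final, P = res$P_final,
                              Z = res$Z_final,
                              complete_loglik = res$complete_loglik_final),
                 allele_maps = enc$maps, seed = seed,
                 alpha = alpha, lambda = lambda,
                 burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations)),
            class = "cluster_run")
}

# recode each locus' allele codes to 1..A; returns n x 2L matrix, 0 = missing
encode_alleles <- function(table) {
  n <- n_samples(table); L <- n_loci(table)
  geno <- matrix(0L, n, 2 * L)
  maps <- vector("list", L)
  for (l in seq_len(L)) {
    obs <- sort(unique(c(table$calls[, l, 1], table$calls[, l, 2])))
    obs <- obs[!is.na(obs)]
    maps[[l]] <- obs
    for (c2 in 1:2) {
      v <- match(table$calls[, l, c2], obs)
      v[is.na(v)] <- 0L
      geno[, 2 * (l - 1) + c2] <- v
    }
  }
  names(maps) <- table$loci
  list(geno = geno, n_alleles = vapply(maps, function(m) max(length(m), 1L),
                                       integer(1)),
       maps = maps)
}

#' Model evidence estimate L(K) from a run's likelihood trace
#'
#' The standard estimator of the log model evidence used for choosing `K`:
#' \deqn{L(K) = \overline{\ell} - \mathrm{var}(\ell)/2}
#' with sample mean and sample variance of the post-burn-in log-likelihood
#' trace.
#'
#' @param run a `cluster_run`, or a numeric log-likelihood trace.
#' @return the scalar estimate.
#' @export
estimate_lnP <- function(run) {
  trace <- if (inherits(run, "cluster_run")) run$loglik_trace else as.numeric(run)
  if (length(trace) < 2) stop("need at least 2 post-burn-in samples")
  mean(trace) - stats::var(trace) / 2
}

#' Evanno Delta-K model choice across replicate runs
#'
#' The second-difference statistic
#' \deqn{\Delta K(k) = \frac{|\overline{L}(k+1) - 2\overline{L}(k) +
#'   \overline{L}(k-1)|}{\mathrm{sd}_{reps} L(k)}}
#' over replicate `L(K)` values, defined for interior `K` with both
#' neighbours present. The chosen `K` is the arg-max over interior `K`
#' (ties to the smaller `K`, with a warning). With fewer than three
#' consecutive `K` values the choice falls back to the `K` maximising mean
#' `L(K)`.
#'
#' @param lnP data.frame with columns `K` and `lnP` (one row per run), or a
#'   list of `cluster_run`s (their `L(K)` computed via [estimate_lnP()]).
#' @return list with `table` (per-K mean, sd, `delta_K`), `chosen_K`,
#'   `method` (`"delta_K"` or `"max_mean_lnP"`).
#' @export
evanno_delta_k <- function(lnP) {
  if (is.list(lnP) && !is.data.frame(lnP)) {
    lnP <- data.frame(K = vapply(lnP, function(r) r$K, integer(1)),
                      lnP = vapply(lnP, estimate_lnP, numeric(1)))
  }
  stopifnot(all(c("K", "lnP") %in% names(lnP)))
  Ks <- sort(unique(lnP$K))
  tab <- data.frame(
    K = Ks,
    n_reps = vapply(Ks, function(k) sum(lnP$K == k), integer(1)),
    mean_lnP = vapply(Ks, function(k) mean(lnP$lnP[lnP$K == k]), numeric(1)),
    sd_lnP = vapply(Ks, function(k) stats::sd(lnP$lnP[lnP$K == k]), numeric(1)))
  tab$delta_K <- NA_real_
  consecutive <- length(Ks) >= 3 && all(diff(Ks) == 1)
  if (consecutive) {
    for (r in 2:(nrow(tab) - 1)) {
      if (tab$K[r - 1] != tab$K[r] - 1 || tab$K[r + 1] != tab$K[r] + 1) next
      second_diff <- abs(tab$mean_lnP[r + 1] - 2 * tab$mean_lnP[r] +
                           tab$mean_lnP[r - 1])
      if (is.na(tab$sd_lnP[r]) || tab$sd_lnP[r] == 0) {
        warning(sprintf(
          "delta K undefined at K = %d (zero replicate spread); excluded",
          tab$K[r]))
        next
      }
      tab$delta_K[r] <- second_diff / tab$sd_lnP[r]
    }
  }
  if (any(!is.na(tab$delta_K))) {
    best <- which(tab$delta_K == max(tab$delta_K, na.rm = TRUE))
    if (length(best) > 1) {
      warning("delta K tie; choosing the smaller K")
      best <- best[1]
    }
    list(table = tab, chosen_K = tab$K[best[1]], method = "delta_K")
  } else {
    list(table = tab, chosen_K = tab$K[which.max(tab$mean_lnP)],
         method = "max_mean_lnP")
  }
}

# all permutations of 1..k (k! rows); fine for k <= 8
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  row <- 0L
  for (pos in seq_len(k)) {
    for (s in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- append(sub[s, ], k, after = pos - 1L)
    }
  }
  out
}

# best column permutation of Q against reference (maximise Frobenius inner
# product); exact for K <= 8, greedy above
best_permutation <- function(Q, ref) {
  K <- ncol(Q)
  S <- crossprod(Q, ref) # S[a, b] = sum_i Q[i,a] * ref[i,b]
  if (K <= 8) {
    perms <- all_permutations(K)
    scores <- vapply(seq_len(nrow(perms)), function(r) {
      sum(S[cbind(perms[r, ], seq_len(K))])
    }, numeric(1))
    perms[which.max(scores), ]
  } else {
    perm <- integer(K); used <- logical(K)
    for (b in order(-apply(S, 2, max))) {
      a <- which.max(ifelse(used, -Inf, S[, b]))
      perm[b] <- a; used[a] <- TRUE
    }
    perm
  }
}

#' Align replicate runs at one K and build the consensus memberships
#'
#' Cluster labels are arbitrary within each run (label switching); each
#' run's columns are permuted to best match an incrementally built
#' reference (the running mean of already-aligned runs), exactly over all
#' `K!` permutations for `K <= 8` and greedily above. The consensus is the
#' mean of the aligned membership matrices.
#'
#' @param runs list of `cluster_run`s sharing one `K`.
#' @return list with `consensus_Q`, `aligned` (list of permuted Q
#'   matrices), `permutations`.
#' @export
align_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  Ks <- vapply(runs, function(r) r$K, integer(1))
  if (length(unique(Ks)) != 1) stop("all runs must share the same K")
  K <- Ks[1]
  ref <- runs[[1]]$Q
  aligned <- list(ref)
  perms <- list(seq_len(K))
  if (length(runs) > 1) {
    acc <- ref
    for (r in 2:length(runs)) {
      pm <- best_permutation(runs[[r]]$Q, acc / (r - 1))
      Qa <- runs[[r]]$Q[, pm, drop = FALSE]
      colnames(Qa) <- colnames(ref)
      aligned[[r]] <- Qa
      perms[[r]] <- pm
      acc <- acc + Qa
    }
  }
  consensus <- Reduce(`+`, aligned) / length(aligned)
  list(consensus_Q = consensus, aligned = aligned, permutations = perms)
}

#' Assign individuals to clusters or call them hybrids
#'
#' An individual is assigned to its arg-max cluster when that membership
#' reaches `q_threshold`, and labelled `"hybrid"` otherwise (the community
#' convention threshold 0.8; studies rarely print theirs).
#'
#' @param consensus_Q individuals x K membership matrix (rows sum to 1).
#' @param q_threshold assignment threshold in (0.5, 1].
#' @param populations optional character vector (per individual) for
#'   per-population frequency tabulation.
#' @return list with `assignments` (named character vector), `frequencies`
#'   (overall proportions incl. hybrids) and `by_population` (matrix of
#'   per-population proportions, rows summing to 1).
#' @export
assign_memberships <- function(consensus_Q, q_threshold = 0.8,
                               populations = NULL) {
  if (q_threshold <= 0.5 || q_threshold > 1) {
    stop("q_threshold must lie in (0.5, 1]")
  }
  K <- ncol(consensus_Q)
  labs <- colnames(consensus_Q)
  if (is.null(labs)) labs <- paste0("cluster", seq_len(K))
  amax <- max.col(consensus_Q, ties.method = "first")
  qmax <- consensus_Q[cbind(seq_len(nrow(consensus_Q)), amax)]
  assignments <- ifelse(qmax >= q_threshold, labs[amax], "hybrid")
  names(assignments) <- rownames(consensus_Q)
  lev <- c(labs, "hybrid")
  freq <- table(factor(assignments, levels = lev)) / length(assignments)
  by_pop <- NULL
  if (!is.null(populations)) {
    by_pop <- t(vapply(split(assignments, populations), function(a) {
      as.numeric(table(factor(a, levels = lev))) / length(a)
    }, numeric(length(lev))))
    colnames(by_pop) <- lev
  }
  list(assignments = assignments, frequencies = as.numeric(freq),
       frequency_labels = lev, by_population = by_pop)
}

#' Concordance between recorded lineage and genetic cluster
#'
#' Cross-tabulates recorded lineage priors against assigned clusters and
#' lists the discordant individuals: those whose assigned cluster's modal
#' lineage differs from their own recorded lineage (a lineage may span
#' several clusters — e.g. an internally substructured founder lineage —
#' so clusters, not lineages, anchor the mapping). Hybrids and individuals
#' without a prior are excluded.
#'
#' @param assignments named character vector from [assign_memberships()].
#' @param lineage_prior named character vector of recorded lineages.
#' @return list with `table` (lineage x cluster cross-tabulation),
#'   `cluster_lineage` (modal lineage per cluster) and `mismatches`
#'   data.frame.
#' @export
lineage_concordance <- function(assignments, lineage_prior) {
  ids <- intersect(names(assignments), names(lineage_prior))
  ids <- ids[!is.na(lineage_prior[ids])]
  if (!length(ids)) stop("no individuals with lineage priors")
  a <- assignments[ids]; p <- lineage_prior[ids]
  tab <- table(lineage = p, cluster = a)
  core <- a != "hybrid"
  cl_lin <- vapply(split(p[core], a[core]), function(v) {
    names(sort(table(v), decreasing = TRUE))[1]
  }, character(1))
  mism <- ids[core & cl_lin[a] != p]
  list(table = tab, cluster_lineage = cl_lin,
       mismatches = data.frame(individual_id = mism,
                               lineage_prior = p[mism],
                               cluster = a[mism],
                               cluster_lineage = cl_lin[a[mism]],
                               row.names = NULL))
}

#' Full clustering scan: replicate runs across K, Evanno choice, consensus
#'
#' Runs [gibbs_admixture()] for every `K` in `k_range` with `replicates`
#' chains each (distinct seeds derived from `seed`), estimates `L(K)`,
#' applies [evanno_delta_k()], aligns the replicate runs at the chosen `K`
#' and assigns memberships.
#'
#' @param table a [genotype_table()].
#' @param k_range integer vector of K values (consecutive for Delta K).
#' @param replicates chains per K.
#' @param seed base seed; run `r` at `K = k` uses `seed + 1000 * k + r`.
#' @param q_threshold hybrid-assignment threshold.
#' @param alpha membership-prior parameter used for the scan. The scan
#'   default (0.1) is deliberately sharper than [gibbs_admixture()]'s flat
#'   1.0: the reference clustering tools infer alpha from the data and land
#'   near small values for distinct populations, and a flat prior blurs Q
#'   at the true K enough to depress its model-evidence gain, biasing the
#'   Delta-K choice toward lower K.
#' @param ... passed to [gibbs_admixture()] (`burn_in`, `iterations`, ...).
#' @return a `cluster_result`: list with `runs`, `lnP` data.frame,
#'   `evanno`, `chosen_K`, `consensus_Q`, `assignment`, `by_population`.
#' @export
run_structure_scan <- function(table, k_range = 1:6, replicates = 5,
                               seed = 1, q_threshold = 0.8, alpha = 0.1,
                               ...) {
  runs <- list()
  lnP <- data.frame(K = integer(), replicate = integer(), lnP = numeric())
  for (k in k_range) {
    for (r in seq_len(replicates)) {
      run <- gibbs_admixture(table, K = k, seed = seed + 1000 * k + r,
                             alpha = alpha, ...)
      runs[[length(runs) + 1L]] <- run
      lnP <- rbind(lnP, data.frame(K = k, replicate = r,
                                   lnP = estimate_lnP(run)))
    }
  }
  ev <- evanno_delta_k(lnP[, c("K", "lnP")])
  kstar <- ev$chosen_K
  at_k <- runs[vapply(runs, function(r) r$K, integer(1)) == kstar]
  al <- align_runs(at_k)
  asg <- assign_memberships(al$consensus_Q, q_threshold = q_threshold,
                            populations = table$samples$population)
  structure(list(runs = runs, lnP = lnP, evanno = ev, chosen_K = kstar,
                 consensus_Q = al$consensus_Q, assignment = asg,
                 by_population = asg$by_population, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: chosen K = %d (%s)\n", x$chosen_K,
              x$evanno$method))
  print(round(x$evanno$table, 2), row.names = FALSE)
  invisible(x)
}

#' Stacked-bar membership plot
#'
#' The classic clustering visual: one bar per individual, partitioned by
#' cluster membership, grouped by population.
#'
#' @param consensus_Q individuals x K membership matrix.
#' @param populations optional grouping vector (per individual).
#' @return a ggplot object.
#' @export
plot_membership <- function(consensus_Q, populations = NULL) {
  ids <- rownames(consensus_Q)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(consensus_Q)))
  labs <- colnames(consensus_Q)
  if (is.null(labs)) labs <- paste0("cluster", seq_len(ncol(consensus_Q)))
  df <- data.frame(
    individual = rep(ids, times = ncol(consensus_Q)),
    cluster = rep(labs, each = nrow(consensus_Q)),
    q = as.numeric(consensus_Q),
    population = if (is.null(populations)) "all"
                 else rep(populations, times = ncol(consensus_Q)))
  df$individual <- factor(df$individual, levels = ids)
  ggplot2::ggplot(df, ggplot2::aes(x = individual, y = q, fill = cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~ population, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "membership (Q)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
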