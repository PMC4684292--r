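#' Filter samples by number of loci successfully typed
#'
#' Non-invasive studies discard samples whose DNA quality is too poor; the
#' standard criterion is a minimum number of successfully typed loci
#' (e.g. at least 7 of 9).
#'
#' @param table a [genotype_table()].
#' @param min_loci minimum non-missing locus calls required to pass.
#' @return list with `passed` (the subset table), `report` (data.frame
#'   `n_samples_in`, `n_passing_filter`) and `typed` (per-sample counts).
#' @export
filter_by_loci_typed <- function(table, min_loci) {
  if (min_loci > n_loci(table)) {
    stop("min_loci cannot exceed the number of loci")
  }
  typed <- loci_typed(table)
  keep <- typed >= min_loci
  list(passed = gt_subset(table, samples = which(keep)),
       report = data.frame(n_samples_in = n_samples(table),
                           n_passing_filter = sum(keep)),
       typed = typed)
}

#' Probability of identity for unrelated individuals and for siblings
#'
#' The probability that two individuals drawn from a population in
#' Hardy-Weinberg proportions share an identical multilocus genotype.
#' Per locus, for unrelated pairs
#' \deqn{P = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2}
#' and for full siblings
#' \deqn{P_{sib} = 0.25 + 0.5 \sum_i p_i^2 + 0.5 (\sum_i p_i^2)^2
#'       - 0.25 \sum_i p_i^4.}
#' Multilocus values are products across loci. These govern whether
#' identical genotypes can safely be collapsed into one individual.
#'
#' @param freqs list of per-locus allele-frequency vectors.
#' @return list with `p_id`, `p_id_sib` (multilocus products) and
#'   `per_locus` data.frame.
#' @export
probability_of_identity <- function(freqs) {
  if (!is.list(freqs)) freqs <- list(freqs)
  per <- vapply(freqs, function(p) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("allele-frequency vectors must sum to 1")
    }
    s2 <- sum(p^2); s4 <- sum(p^4)
    pid <- s4 + sum((2 * outer(p, p))[upper.tri(diag(length(p)))]^2)
    psib <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
    c(pid, psib)
  }, numeric(2))
  list(p_id = prod(per[1, ]), p_id_sib = prod(per[2, ]),
       per_locus = data.frame(locus = seq_along(freqs),
                              p_id = per[1, ], p_id_sib = per[2, ]))
}

# mismatching loci between two call slices (L x 2), counting only loci
# typed in both; returns c(mismatches, comparisons)
pair_mismatch <- function(a, b) {
  ok <- !is.na(a[, 1]) & !is.na(b[, 1])
  if (!any(ok)) return(c(0L, 0L))
  mm <- (a[ok, 1] != b[ok, 1]) | (a[ok, 2] != b[ok, 2])
  c(sum(mm), sum(ok))
}

#' Group samples whose multilocus genotypes match
#'
#' Two samples match when, across loci typed in both, the number of
#' differing unordered allele pairs is at most `max_mismatch` (default 0:
#' identical genotypes, the conservative field practice). Matching samples
#' are grouped by connected components and each group is treated as one
#' individual. Optional mtDNA haplotypes and localities corroborate the
#' grouping, mirroring the field check that duplicates share a haplotype
#' and collection site.
#'
#' @param table a filtered [genotype_table()].
#' @param max_mismatch maximum mismatching loci tolerated within a match.
#' @param haplotypes optional named character vector (by sample id).
#' @param localities optional named character vector (by sample id);
#'   defaults to the table's `locality` column.
#' @param min_overlap minimum loci typed in both samples for a comparison
#'   to be meaningful (pairs below it never match).
#' @return list with `groups` (list of sample-id vectors), `individual_of`
#'   (named vector sample -> individual label), `n_individuals`, and
#'   `corroboration` data.frame (per group: same haplotype? same
#'   locality?).
#' @export
match_genotypes <- function(table, max_mismatch = 0, haplotypes = NULL,
                            localities = NULL, min_overlap = 1) {
  n <- n_samples(table)
  if (max_mismatch >= n_loci(table)) {
    stop("max_mismatch must be smaller than the number of loci")
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        mc <- pair_mismatch(table$calls[i, , , drop = TRUE],
                            table$calls[j, , , drop = TRUE])
        if (mc[2] >= min_overlap && mc[1] <= max_mismatch) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- table$samples$sample_id
  groups <- split(ids, roots)
  names(groups) <- sprintf("ind_%03d", seq_along(groups))
  individual_of <- stats::setNames(rep(names(groups), lengths(groups)),
                                   unlist(groups, use.names = FALSE))
  if (is.null(localities)) {
    localities <- stats::setNames(table$samples$locality, ids)
  }
  corr <- data.frame(
    group = names(groups), n_samples = lengths(groups),
    same_haplotype = vapply(groups, function(g) {
      if (is.null(haplotypes)) return(NA)
      h <- haplotypes[g]; h <- h[!is.na(h)]
      length(unique(h)) <= 1
    }, logical(1)),
    same_locality = vapply(groups, function(g) {
      lc <- localities[g]; lc <- lc[!is.na(lc)]
      length(unique(lc)) <= 1
    }, logical(1)),
    row.names = NULL)
  list(groups = groups, individual_of = individual_of,
       n_individuals = length(groups), corroboration = corr)
}

#' Consensus genotype across replicates
#'
#' Per locus, an allele is *confirmed* if observed in at least two
#' replicates, or in the sole replicate typed at the locus. The consensus
#' is the confirmed heterozygote when two alleles are confirmed; with one
#' confirmed allele and exactly two replicates, a second allele seen once
#' alongside it wins (heterozygote-wins tie rule: allelic dropout, not
#' false alleles, dominates faecal genotyping error); with three or more
#' replicates, singleton alleles are demoted and the confirmed homozygote
#' stands. Conflicting singleton-only observations leave the locus missing.
#'
#' @param replicates a [genotype_table()] whose rows are replicates of one
#'   sample or individual.
#' @return list with `genotype` (L x 2 matrix), `low_confidence` (logical
#'   per locus: single-replicate support) and `n_replicates` per locus.
#' @export
consensus_genotype <- function(replicates) {
  L <- n_loci(replicates)
  out <- matrix(NA_integer_, L, 2)
  lowconf <- logical(L)
  nrep <- integer(L)
  for (l in seq_len(L)) {
    calls <- replicates$calls[, l, , drop = FALSE]
    ok <- which(!is.na(calls[, 1, 1]))
    nrep[l] <- length(ok)
    if (!length(ok)) next
    if (length(ok) == 1) {
      out[l, ] <- calls[ok, 1, ]
      lowconf[l] <- TRUE
      next
    }
    support <- table(unlist(lapply(ok, function(i) unique(calls[i, 1, ]))))
    support <- sort(support, decreasing = TRUE)
    alleles <- as.integer(names(support))
    confirmed <- alleles[support >= 2]
    singles <- alleles[support == 1]
    if (length(confirmed) >= 2) {
      top <- order(-support[support >= 2], confirmed)[1:2]
      out[l, ] <- sort(confirmed[top])
    } else if (length(confirmed) == 1) {
      if (length(ok) == 2 && length(singles) == 1) {
        out[l, ] <- sort(c(confirmed, singles)) # heterozygote wins
      } else {
        out[l, ] <- c(confirmed, confirmed)
      }
    } else {
      # no confirmed allele: conflicting single observations stay missing
      out[l, ] <- NA_integer_
    }
  }
  list(genotype = out, low_confidence = lowconf, n_replicates = nrep)
}

#' Estimate allelic dropout and false-allele rates from replicates
#'
#' Rates are defined per replicate observation against the consensus
#' genotype. Per locus: the dropout rate is the fraction of replicate
#' observations of consensus-heterozygous loci that show exactly one of the
#' two consensus alleles; the false-allele rate is the fraction of all
#' replicate locus observations containing an allele absent from the
#' consensus. Means are unweighted across loci; a locus (or dataset) with
#' no heterozygous consensus has an undefined (`NA`) dropout rate, never a
#' silent zero.
#'
#' @param replicate_groups list of [genotype_table()]s, one per individual
#'   (or field sample), each holding that individual's replicates.
#' @param consensus optional list of consensus results from
#'   [consensus_genotype()]; computed when absent.
#' @return list with `per_locus` data.frame (`locus`, `dropout`,
#'   `false_allele`, `n_het_obs`, `n_obs`), `mean_dropout`,
#'   `mean_false_allele`.
#' @export
estimate_error_rates <- function(replicate_groups, consensus = NULL) {
  stopifnot(length(replicate_groups) >= 1)
  loci <- replicate_groups[[1]]$loci
  L <- length(loci)
  if (is.null(consensus)) {
    consensus <- lapply(replicate_groups, consensus_genotype)
  }
  het_obs <- het_drop <- obs <- fa <- integer(L)
  for (g in seq_along(replicate_groups)) {
    reps <- replicate_groups[[g]]
    cons <- consensus[[g]]$genotype
    for (l in seq_len(L)) {
      ca <- cons[l, ]
      if (anyNA(ca)) next
      for (i in seq_len(n_samples(reps))) {
        r <- reps$calls[i, l, ]
        if (anyNA(r)) next
        obs[l] <- obs[l] + 1L
        if (any(!r %in% ca)) fa[l] <- fa[l] + 1L
        if (ca[1] != ca[2]) {
          het_obs[l] <- het_obs[l] + 1L
          seen <- unique(r[r %in% ca])
          if (length(seen) == 1) het_drop[l] <- het_drop[l] + 1L
        }
      }
    }
  }
  dropout <- ifelse(het_obs > 0, het_drop / het_obs, NA_real_)
  false_allele <- ifelse(obs > 0, fa / obs, NA_real_)
  list(per_locus = data.frame(locus = loci, dropout = dropout,
                              false_allele = false_allele,
                              n_het_obs = het_obs, n_obs = obs),
       mean_dropout = if (all(is.na(dropout))) NA_real_
                      else mean(dropout, na.rm = TRUE),
       mean_false_allele = if (all(is.na(false_allele))) NA_real_
                           else mean(false_allele, na.rm = TRUE))
}

#' Consolidate a replicate set into individuals: the full QC stage
#'
#' Runs the whole non-invasive workflow: per-field-sample consensus calls,
#' completeness filtering, genotype matching into individuals, error-rate
#' estimation against consensus, and the probability-of-identity check on
#' the consolidated individuals' allele frequencies.
#'
#' @param reps a `replicate_set` from [simulate_noninvasive_replicates()],
#'   or any [genotype_table()] with `field_sample` + `replicate` metadata
#'   columns.
#' @param min_loci completeness threshold (default 7, the usual
#'   seven-of-nine criterion).
#' @param max_mismatch matching tolerance (default 0).
#' @param haplotypes optional named mtDNA haplotypes per field sample for
#'   corroboration.
#' @return a `qc_report` list: `n_samples_in`, `n_passing_filter`,
#'   `n_individuals`, `p_id`, `p_id_sib`, error-rate block, `match`,
#'   `individuals` (consensus [genotype_table()], one row per individual).
#' @export
noninvasive_qc <- function(reps, min_loci = 7, max_mismatch = 0,
                           haplotypes = NULL) {
  rep_table <- if (inherits(reps, "replicate_set")) reps$table else reps
  if (is.null(rep_table$samples$field_sample)) {
    stop("replicate table needs a field_sample metadata column")
  }
  fs <- unique(rep_table$samples$field_sample)
  # consensus per field sample
  cons_calls <- array(NA_integer_, dim = c(length(fs), n_loci(rep_table), 2))
  cons_list <- vector("list", length(fs))
  groups_list <- vector("list", length(fs))
  for (s in seq_along(fs)) {
    sub <- gt_subset(rep_table,
                     samples = which(rep_table$samples$field_sample == fs[s]))
    groups_list[[s]] <- sub
    cons_list[[s]] <- consensus_genotype(sub)
    cons_calls[s, , ] <- cons_list[[s]]$genotype
  }
  meta_first <- rep_table$samples[match(fs, rep_table$samples$field_sample), ]
  cons_table <- genotype_table(
    data.frame(sample_id = fs,
               individual_id = meta_first$individual_id,
               population = meta_first$population,
               locality = meta_first$locality,
               sex = meta_first$sex, source = "faeces",
               stringsAsFactors = FALSE),
    rep_table$loci, cons_calls)

  flt <- filter_by_loci_typed(cons_table, min_loci)
  match <- match_genotypes(flt$passed, max_mismatch = max_mismatch,
                           haplotypes = haplotypes)

  # error rates from replicates of passing field samples
  keep <- fs %in% flt$passed$samples$sample_id
  err <- estimate_error_rates(groups_list[keep], cons_list[keep])

  # one consensus genotype per matched individual (replicates across its
  # field samples pooled)
  ind_ids <- names(match$groups)
  ind_calls <- array(NA_integer_, dim = c(length(ind_ids), n_loci(rep_table), 2))
  for (g in seq_along(match$groups)) {
    rows <- which(rep_table$samples$field_sample %in% match$groups[[g]])
    ind_calls[g, , ] <- consensus_genotype(
      gt_subset(rep_table, samples = rows))$genotype
  }
  first_fs <- vapply(match$groups, `[`, character(1), 1)
  meta_ind <- flt$passed$samples[match(first_fs, flt$passed$samples$sample_id), ]
  individuals <- genotype_table(
    data.frame(sample_id = ind_ids,
               individual_id = meta_ind$individual_id,
               population = meta_ind$population,
               locality = meta_ind$locality, sex = meta_ind$sex,
               source = "faeces", stringsAsFactors = FALSE),
    rep_table$loci, ind_calls)

  freqs <- lapply(seq_len(n_loci(individuals)), function(l) {
    af <- try(allele_frequencies(individuals, l), silent = TRUE)
    if (inherits(af, "try-error")) NULL else af$freqs
  })
  freqs <- Filter(Negate(is.null), freqs)
  pid <- if (length(freqs)) probability_of_identity(freqs)
         else list(p_id = NA_real_, p_id_sib = NA_real_)

  structure(list(n_samples_in = n_samples(cons_table),
                 n_passing_filter = flt$report$n_passing_filter,
                 n_individuals = match$n_individuals,
                 p_id = pid$p_id, p_id_sib = pid$p_id_sib,
                 error_rates = err, match = match,
                 individuals = individuals,
                 consensus_samples = cons_table,
                 settings = list(min_loci = min_loci,
                                 max_mismatch = max_mismatch)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("non-invasive QC: %d samples in, %d passed (>= %d loci), %d individuals\n",
              x$n_samples_in, x$n_passing_filter, x$settings$min_loci,
              x$n_individuals))
  cat(sprintf("P_ID = %.3g, P_ID(sib) = %.3g\n", x$p_id, x$p_id_sib))
  cat(sprintf("mean dropout = %s, mean false-allele = %s\n",
              format(x$error_rates$mean_dropout, digits = 3),
              format(x$error_rates$mean_false_allele, digits = 3)))
  invisible(x)
}
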