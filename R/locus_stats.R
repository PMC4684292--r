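#' Observed allele frequencies at one locus
#'
#' Frequencies are computed from observed gene copies: two per typed
#' diploid call (hemizygous calls recorded as homozygotes thus contribute
#' two copies of their single allele — the scoring artefact the sex-linkage
#' screen targets).
#'
#' @param table a [genotype_table()].
#' @param locus locus name or index.
#' @return list with `freqs` (named frequency vector over observed
#'   alleles), `n_alleles`, `n_typed` (typed individuals), `counts`.
#' @export
allele_frequencies <- function(table, locus) {
  l <- locus_index(table, locus)
  a <- table$calls[, l, 1]; b <- table$calls[, l, 2]
  copies <- c(a[!is.na(a)], b[!is.na(b)])
  if (!length(copies)) stop(sprintf("locus %s has no typed calls", table$loci[l]))
  counts <- table(factor(copies, levels = sort(unique(copies))))
  freqs <- as.numeric(counts) / sum(counts)
  names(freqs) <- names(counts)
  list(freqs = freqs, n_alleles = length(freqs),
       n_typed = sum(!is.na(a)), counts = as.integer(counts))
}

locus_index <- function(table, locus) {
  l <- if (is.character(locus)) match(locus, table$loci) else as.integer(locus)
  if (is.na(l) || l < 1 || l > n_loci(table)) {
    stop(sprintf("unknown locus: %s", locus))
  }
  l
}

#' Expected and observed heterozygosity at one locus
#'
#' `h_obs` is the fraction of typed calls that are heterozygous. `h_exp`
#' is the unbiased gene diversity
#' \deqn{H_E = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)}
#' with `n` typed individuals — the small-sample-corrected estimator used
#' by the classic microsatellite toolkits.
#'
#' @inheritParams allele_frequencies
#' @return list with `h_exp`, `h_obs`, `n_typed`.
#' @export
heterozygosities <- function(table, locus) {
  l <- locus_index(table, locus)
  af <- allele_frequencies(table, l)
  n <- af$n_typed
  if (n < 2) stop("need at least 2 typed individuals")
  a <- table$calls[, l, 1]; b <- table$calls[, l, 2]
  ok <- !is.na(a)
  h_obs <- mean(a[ok] != b[ok])
  h_exp <- (2 * n / (2 * n - 1)) * (1 - sum(af$freqs^2))
  list(h_exp = h_exp, h_obs = h_obs, n_typed = n)
}

#' Inbreeding coefficient F_IS
#'
#' Nei's within-population fixation index, `1 - H_O / H_E`: positive for a
#' heterozygote deficit (inbreeding, substructure, null alleles or sex
#' linkage), negative for a heterozygote excess.
#'
#' @param h_exp,h_obs expected and observed heterozygosity.
#' @return F_IS, or `NA` when `h_exp` is 0 (monomorphic locus).
#' @export
fis <- function(h_exp, h_obs) {
  if (is.na(h_exp) || h_exp <= 0) return(NA_real_)
  1 - h_obs / h_exp
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up FDR control across the per-locus Hardy-Weinberg tests of one
#' population table (delegates to [stats::p.adjust()]).
#'
#' @param p numeric p-values.
#' @param q FDR level in (0,1).
#' @return logical vector: significant after FDR correction.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must lie in (0,1)")
  if (!length(p)) return(logical(0))
  stats::p.adjust(p, method = "BH") <= q
}

#' Per-locus diversity summary of one population table
#'
#' Assembles, per locus: allele number `N`, unbiased expected and observed
#' heterozygosity, `F_IS`, the exact Hardy-Weinberg p-value with a BH-FDR
#' significance flag, and the maximum-likelihood null-allele frequency —
#' plus two unweighted average rows, one over all loci and one excluding a
#' stated set (typically the sex-linked loci flagged by
#' [screen_all_loci()]).
#'
#' @param table a one-population [genotype_table()].
#' @param exclude_loci character vector of locus names excluded from the
#'   starred average row (must be a subset of the table's loci).
#' @param q FDR level for the HWE significance flags.
#' @param hwe_args list of extra arguments for [hwe_exact_test()].
#' @param naf_args list of extra arguments for [null_allele_ml()].
#' @return a `population_summary`: list with `per_locus` data.frame,
#'   `average` (all loci), `average_excluding` (the starred row) and
#'   `exclude_loci`.
#' @export
summarize_population <- function(table, exclude_loci = character(),
                                 q = 0.05, hwe_args = list(),
                                 naf_args = list()) {
  if (!all(exclude_loci %in% table$loci)) {
    stop("exclude_loci must be a subset of the table's loci")
  }
  L <- n_loci(table)
  rows <- lapply(seq_len(L), function(l) {
    af <- try(allele_frequencies(table, l), silent = TRUE)
    if (inherits(af, "try-error")) {
      return(data.frame(locus = table$loci[l], n_alleles = NA_integer_,
                        n_typed = 0L, h_exp = NA_real_, h_obs = NA_real_,
                        f_is = NA_real_, hwe_p = NA_real_, naf = NA_real_))
    }
    hz <- heterozygosities(table, l)
    counts <- genotype_counts(table, l)
    hwe <- do.call(hwe_exact_test, c(list(counts), hwe_args))
    n_missing <- sum(is.na(table$calls[, l, 1]))
    naf <- do.call(null_allele_ml, c(list(counts, n_blank = n_missing),
                                     naf_args))
    data.frame(locus = table$loci[l], n_alleles = af$n_alleles,
               n_typed = af$n_typed, h_exp = hz$h_exp, h_obs = hz$h_obs,
               f_is = fis(hz$h_exp, hz$h_obs), hwe_p = hwe$p_value,
               naf = naf$naf)
  })
  per_locus <- do.call(rbind, rows)
  per_locus$hwe_significant_fdr <- fdr_correct(per_locus$hwe_p, q = q)
  avg_over <- function(idx) {
    cols <- c("n_alleles", "h_exp", "h_obs", "f_is", "naf")
    out <- lapply(cols, function(cn) mean(per_locus[[cn]][idx], na.rm = TRUE))
    names(out) <- cols
    as.data.frame(out)
  }
  keep <- !per_locus$locus %in% exclude_loci
  structure(list(per_locus = per_locus,
                 average = avg_over(rep(TRUE, L)),
                 average_excluding = avg_over(keep),
                 exclude_loci = exclude_loci),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  df <- x$per_locus
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 3))
  print(df, row.names = FALSE)
  cat("Average          :", fmt_avg(x$average), "\n")
  cat(sprintf("Average (w/o %s): %s\n",
              paste(x$exclude_loci, collapse = "/"),
              fmt_avg(x$average_excluding)))
  invisible(x)
}

fmt_avg <- function(a) {
  paste(sprintf("%s=%.3f", names(a), unlist(a)), collapse = " ")
}

#' Genotype counts at one locus
#'
#' Tabulates unordered genotype counts, the input of the exact HWE test
#' and the null-allele estimator.
#'
#' @inheritParams allele_frequencies
#' @return a `genotype_counts` object: list with `alleles` (sorted codes),
#'   `counts` (named vector, names `"i/j"` with `i <= j`), `n` typed
#'   individuals.
#' @export
genotype_counts <- function(table, locus) {
  l <- locus_index(table, locus)
  a <- table$calls[, l, 1]; b <- table$calls[, l, 2]
  ok <- !is.na(a)
  alleles <- sort(unique(c(a[ok], b[ok])))
  key <- paste0(a[ok], "/", b[ok])
  counts <- table(key)
  structure(list(alleles = alleles,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 n = sum(ok)),
            class = "genotype_counts")
}
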