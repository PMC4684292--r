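#' Exact test of Hardy-Weinberg proportions at one locus
#'
#' Conditional exact test: given the observed allele counts, each genotype
#' table has probability
#' \deqn{P = \frac{n!\,\prod_a m_a!\,2^h}{(2n)!\,\prod_{g} n_g!}}
#' (`h` = heterozygote count), and the p-value is the total probability of
#' tables no more probable than the observed one. The full table space is
#' enumerated when it is small enough; otherwise the null distribution is
#' sampled by randomly pairing the `2n` observed gene copies (Monte Carlo,
#' fixed replicate count, seeded).
#'
#' @param counts a [genotype_counts()] object (or a genotype table plus
#'   locus via [genotype_counts()]).
#' @param enumeration_bound enumerate completely when the number of tables
#'   does not exceed this (default 1e6).
#' @param n_sim Monte Carlo tables used above the bound (default 1e5).
#' @param seed optional seed for the Monte Carlo mode.
#' @return list with `p_value`, `method` (`"enumeration"`, `"monte_carlo"`
#'   or `"monomorphic"`), and `n_tables`/`n_sim` as applicable. Monomorphic
#'   loci return `p_value = 1` by convention.
#' @export
hwe_exact_test <- function(counts, enumeration_bound = 1e6, n_sim = 1e5,
                           seed = NULL) {
  stopifnot(inherits(counts, "genotype_counts"))
  k <- length(counts$alleles)
  if (k < 2 || counts$n < 2) {
    return(list(p_value = 1, method = "monomorphic"))
  }
  gmat <- counts_to_triangle(counts)
  m <- allele_copy_counts(counts)
  enum <- .hwe_enumerate_cpp(m, gmat, enumeration_bound)
  if (!enum$aborted) {
    return(list(p_value = enum$p_value, method = "enumeration",
                n_tables = enum$n_tables))
  }
  if (!is.null(seed)) set.seed(seed)
  mc <- .hwe_mc_cpp(m, gmat, as.integer(n_sim))
  list(p_value = mc$p_value, method = "monte_carlo", n_sim = mc$n_sim)
}

# genotype_counts -> upper-triangle vector in row-major (i<=j) order of
# allele indices
counts_to_triangle <- function(counts) {
  k <- length(counts$alleles)
  g <- matrix(0L, k, k)
  prs <- strsplit(names(counts$counts), "/", fixed = TRUE)
  for (t in seq_along(prs)) {
    i <- match(as.integer(prs[[t]][1]), counts$alleles)
    j <- match(as.integer(prs[[t]][2]), counts$alleles)
    g[min(i, j), max(i, j)] <- g[min(i, j), max(i, j)] + counts$counts[t]
  }
  out <- integer(0)
  for (i in seq_len(k)) out <- c(out, g[i, i:k])
  out
}

allele_copy_counts <- function(counts) {
  k <- length(counts$alleles)
  m <- integer(k)
  prs <- strsplit(names(counts$counts), "/", fixed = TRUE)
  for (t in seq_along(prs)) {
    i <- match(as.integer(prs[[t]][1]), counts$alleles)
    j <- match(as.integer(prs[[t]][2]), counts$alleles)
    m[i] <- m[i] + counts$counts[t]
    m[j] <- m[j] + counts$counts[t]
  }
  m
}

#' Build a genotype_counts object directly from genotype count values
#'
#' Convenience constructor for tests and worked examples: supply counts
#' keyed by `"i/j"` allele-pair strings.
#'
#' @param counts named integer vector, names like `"1/1"`, `"1/2"`.
#' @return a `genotype_counts` object.
#' @export
as_genotype_counts <- function(counts) {
  prs <- strsplit(names(counts), "/", fixed = TRUE)
  alleles <- sort(unique(as.integer(unlist(prs))))
  norm <- vapply(prs, function(p) {
    p <- sort(as.integer(p)); paste0(p[1], "/", p[2])
  }, character(1))
  agg <- tapply(as.integer(counts), norm, sum)
  structure(list(alleles = alleles,
                 counts = stats::setNames(as.integer(agg), names(agg)),
                 n = sum(counts)),
            class = "genotype_counts")
}
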