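#' Collapse aligned sequences into haplotypes
#'
#' Haplotypes are equivalence classes of exact identity on the *included*
#' alignment columns. By default (complete deletion, the convention of the
#' classic DNA-polymorphism toolkits) any column carrying a gap (`-`) or an
#' ambiguity code (anything outside `A`/`C`/`G`/`T`) in any sequence is
#' excluded alignment-wide before comparison; `deletion = "pairwise"`
#' instead excludes sites per pair only where either member is ambiguous
#' (haplotype collapsing still uses the complete-deletion site set so that
#' labels stay well defined).
#'
#' Labels `H1`, `H2`, ... are deterministic: sorted by total count, ties by
#' first occurrence in the input.
#'
#' @param aln a [sequence_alignment()].
#' @param populations optional character vector (per sequence, recycled
#'   names from the alignment) for per-population counts.
#' @param deletion `"complete"` (default) or `"pairwise"` site handling
#'   for downstream diversity computations.
#' @return a `haplotype_table`: list with `haplotype_of` (named label per
#'   sequence), `representative` (label -> full-length sequence), `counts`
#'   (label x population matrix), `included_sites` (1-based column
#'   indices), `deletion`.
#' @export
collapse_haplotypes <- function(aln, populations = NULL,
                                deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (!length(aln$seqs)) stop("empty alignment")
  mat <- alignment_matrix(aln)
  good <- matrix(mat %in% c("A", "C", "G", "T"), nrow(mat), ncol(mat))
  included <- which(apply(good, 2, all))
  if (!length(included)) stop("no unambiguous alignment columns left")
  key <- apply(mat[, included, drop = FALSE], 1, paste, collapse = "")
  first <- !duplicated(key)
  occ_order <- match(key, key[first])
  tot <- tabulate(occ_order)
  ord <- order(-tot, seq_along(tot)) # by count desc, ties by first occurrence
  rank <- match(seq_along(tot), ord)
  labels <- paste0("H", rank[occ_order])
  names(labels) <- rownames(mat)
  if (is.null(populations)) populations <- rep("all", length(labels))
  lab_lev <- paste0("H", seq_len(sum(first)))
  counts <- table(factor(labels, levels = lab_lev), populations)
  rep_seq <- aln$seqs[first]
  names(rep_seq) <- labels[first]
  rep_seq <- rep_seq[lab_lev]
  structure(list(haplotype_of = labels, representative = rep_seq,
                 counts = unclass(counts), included_sites = included,
                 deletion = deletion, n_seqs = length(labels)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d sequences, %d haplotypes, %d included sites\n",
              x$n_seqs, nrow(x$counts), length(x$included_sites)))
  print(x$counts)
  invisible(x)
}

#' Haplotype diversity
#'
#' The unbiased probability that two sequences drawn without replacement
#' carry different haplotypes:
#' \deqn{H_D = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' with haplotype frequencies `p_i = count_i / n`.
#'
#' @param counts integer vector of haplotype counts (one population).
#' @return the scalar `H_D`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- as.numeric(counts[counts > 0])
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs at least 2 sequences")
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Nucleotide diversity and polymorphic-site count
#'
#' Average per-site pairwise difference:
#' \deqn{\pi = \frac{\sum_{i<j} d_{ij}}{\binom{n}{2}\,L_{incl}}}
#' where `d_ij` counts differing included sites, and `N_P` is the number of
#' included sites with at least two states. Under complete deletion the
#' included site set is alignment-wide; under pairwise deletion each pair
#' is compared on its own unambiguous sites (each pair's differences then
#' scaled to the alignment-wide included length).
#'
#' @param aln a [sequence_alignment()].
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return list with `nd` (per-site nucleotide diversity), `n_polymorphic`,
#'   `n_included_sites`, `n_seqs`.
#' @export
nucleotide_diversity <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (length(aln$seqs) < 2) stop("nucleotide diversity needs >= 2 sequences")
  mat <- alignment_matrix(aln)
  good <- matrix(mat %in% c("A", "C", "G", "T"), nrow(mat), ncol(mat))
  included <- which(apply(good, 2, all))
  if (!length(included)) stop("no unambiguous alignment columns left")
  n <- nrow(mat)
  if (deletion == "complete") {
    sub <- mat[, included, drop = FALSE]
    np <- sum(apply(sub, 2, function(col) length(unique(col)) > 1))
    dsum <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) dsum <- dsum + sum(sub[i, ] != sub[j, ])
    }
    nd <- dsum / choose(n, 2) / length(included)
  } else {
    sub <- mat[, included, drop = FALSE]
    np <- sum(apply(sub, 2, function(col) length(unique(col)) > 1))
    frac <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- good[i, ] & good[j, ]
        frac <- frac + sum(mat[i, ok] != mat[j, ok]) / sum(ok)
      }
    }
    nd <- frac / choose(n, 2)
  }
  list(nd = nd, n_polymorphic = as.integer(np),
       n_included_sites = length(included), n_seqs = n)
}

#' Shared and unique haplotypes between two populations
#'
#' @param hap a `haplotype_table` whose `counts` has (at least) two
#'   population columns, or a label -> count matrix.
#' @param pop_a,pop_b population column names (defaults: first two).
#' @return data.frame with `n_a`, `n_b`, `shared`, `unique_a`, `unique_b`,
#'   `union` haplotype counts.
#' @export
compare_populations <- function(hap, pop_a = NULL, pop_b = NULL) {
  counts <- if (inherits(hap, "haplotype_table")) hap$counts else hap
  if (ncol(counts) < 2) stop("need two population columns to compare")
  if (is.null(pop_a)) pop_a <- colnames(counts)[1]
  if (is.null(pop_b)) pop_b <- colnames(counts)[2]
  A <- rownames(counts)[counts[, pop_a] > 0]
  B <- rownames(counts)[counts[, pop_b] > 0]
  data.frame(pop_a = pop_a, pop_b = pop_b,
             n_a = length(A), n_b = length(B),
             shared = length(intersect(A, B)),
             unique_a = length(setdiff(A, B)),
             unique_b = length(setdiff(B, A)),
             union = length(union(A, B)))
}

#' Per-population mtDNA diversity summary
#'
#' Assembles, per population: number of sequences `N_S`, alignment length
#' `L`, polymorphic sites `N_P`, haplotypes `N_H`, haplotype diversity
#' `H_D` and nucleotide diversity `N_D`. Site exclusion (and therefore
#' `N_P`, `N_D`) is evaluated within each population on its own sequences.
#'
#' @param aln a [sequence_alignment()] holding all populations' sequences.
#' @param populations character vector, one entry per sequence.
#' @param deletion site-handling mode, see [nucleotide_diversity()].
#' @return list with `summary` data.frame (one row per population),
#'   `haplotypes` (the joint `haplotype_table`, shared label space) and
#'   `comparison` (when exactly two populations, the shared/unique
#'   accounting).
#' @export
summarize_mtdna <- function(aln, populations,
                            deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(length(populations) == length(aln$seqs))
  hap <- collapse_haplotypes(aln, populations, deletion = deletion)
  pops <- colnames(hap$counts)
  rows <- lapply(pops, function(p) {
    idx <- which(populations == p)
    sub <- sequence_alignment(aln$seqs[idx])
    cnt <- hap$counts[, p]
    nd <- if (length(idx) >= 2) nucleotide_diversity(sub, deletion = deletion)
          else list(nd = NA_real_, n_polymorphic = NA_integer_)
    data.frame(population = p, n_seqs = length(idx), length = aln$length,
               n_polymorphic = nd$n_polymorphic,
               n_haplotypes = sum(cnt > 0),
               hap_diversity = if (length(idx) >= 2) haplotype_diversity(cnt)
                               else NA_real_,
               nucleotide_diversity = nd$nd)
  })
  out <- list(summary = do.call(rbind, rows), haplotypes = hap)
  if (length(pops) == 2) out$comparison <- compare_populations(hap)
  structure(out, class = "mtdna_summary")
}

#' @export
print.mtdna_summary <- function(x, ...) {
  df <- x$summary
  df$hap_diversity <- round(df$hap_diversity, 3)
  df$nucleotide_diversity <- signif(df$nucleotide_diversity, 3)
  print(df, row.names = FALSE)
  if (!is.null(x$comparison)) print(x$comparison, row.names = FALSE)
  invisible(x)
}
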