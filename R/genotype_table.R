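#' Construct a diploid multilocus genotype table
#'
#' The central container of the nuclear-DNA stages: a rectangular table of
#' unordered diploid allele pairs (positive integer allele codes) for a set
#' of samples at a set of loci, together with per-sample metadata.
#' Hemizygous calls (females at Z-linked loci) are *recorded* as homozygous
#' diploid calls, reproducing how fragment-analysis software scores them;
#' the sex-linkage screen exists precisely to detect that artefact.
#'
#' @param samples data.frame of per-sample metadata. Must contain
#'   `sample_id` (unique, character). Optional columns `individual_id`,
#'   `population`, `lineage_prior`, `sex` (`"male"`, `"female"` or
#'   `"unknown"`), `locality`, `source` (`"blood"` or `"faeces"`); missing
#'   ones are filled with `NA` / `"unknown"`.
#' @param loci character vector of locus names.
#' @param calls integer array `n_samples x n_loci x 2` of allele codes, or a
#'   list that [as_call_array()] accepts. Missing calls are `NA` in both
#'   slots. Allele order within a pair is not meaningful; pairs are stored
#'   sorted.
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `samples`, `loci`, `calls` (sorted-pair array).
#' @export
#' @examples
#' gt <- genotype_table(
#'   samples = data.frame(sample_id = c("a", "b")),
#'   loci = c("L1", "L2"),
#'   calls = array(c(1L, 2L, 1L, NA, 2L, 2L, 3L, NA), dim = c(2, 2, 2))
#' )
#' n_samples(gt)
genotype_table <- function(samples, loci, calls) {
  stopifnot(is.data.frame(samples), "sample_id" %in% names(samples))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id values must be unique within a genotype table")
  }
  defaults <- list(individual_id = NA_character_, population = NA_character_,
                   lineage_prior = NA_character_, sex = "unknown",
                   locality = NA_character_, source = NA_character_)
  for (nm in names(defaults)) {
    if (is.null(samples[[nm]])) samples[[nm]] <- defaults[[nm]]
    samples[[nm]] <- as.character(samples[[nm]])
  }
  bad_sex <- !samples$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) stop("sex must be 'male', 'female' or 'unknown'")
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("locus names must be unique")
  calls <- as_call_array(calls, nrow(samples), length(loci))
  dimnames(calls) <- list(samples$sample_id, loci, NULL)
  structure(list(samples = samples, loci = loci, calls = calls),
            class = "genotype_table")
}

#' Coerce calls to a sorted allele-pair array
#'
#' @param calls array `n x L x 2` or list of per-sample lists of pairs.
#' @param n,L expected dimensions.
#' @return integer array with each pair sorted (`NA`s last), both slots `NA`
#'   when either allele is missing.
#' @keywords internal
#' @export
as_call_array <- function(calls, n, L) {
  if (is.list(calls)) {
    arr <- array(NA_integer_, dim = c(n, L, 2))
    for (i in seq_len(n)) {
      for (l in seq_len(L)) {
        pr <- calls[[i]][[l]]
        if (!is.null(pr) && length(pr) == 2 && !anyNA(pr)) {
          arr[i, l, ] <- as.integer(pr)
        }
      }
    }
    calls <- arr
  }
  if (!is.array(calls) || length(dim(calls)) != 3 ||
      !all(dim(calls) == c(n, L, 2))) {
    stop("calls must be an n_samples x n_loci x 2 array")
  }
  storage.mode(calls) <- "integer"
  a <- calls[, , 1, drop = FALSE]
  b <- calls[, , 2, drop = FALSE]
  miss <- is.na(a) | is.na(b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  lo[miss] <- NA_integer_; hi[miss] <- NA_integer_
  if (any(!is.na(lo) & lo <= 0L)) stop("allele codes must be positive integers")
  out <- array(NA_integer_, dim = dim(calls))
  out[, , 1] <- lo
  out[, , 2] <- hi
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d loci\n",
              n_samples(x), n_loci(x)))
  pops <- table(x$samples$population, useNA = "ifany")
  if (length(pops)) {
    cat("populations:",
        paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  }
  typed <- mean(!is.na(x$calls[, , 1, drop = FALSE]))
  cat(sprintf("typed calls: %.1f%%\n", 100 * typed))
  invisible(x)
}

#' Number of samples / loci in a genotype table
#' @param x a `genotype_table`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_loci <- function(x) length(x$loci)

#' Subset a genotype table by samples and/or loci
#'
#' @param x a `genotype_table`.
#' @param samples logical/integer/character index into samples (character
#'   matches `sample_id`).
#' @param loci logical/integer/character index into loci.
#' @return the subset `genotype_table`, order following the index.
#' @export
gt_subset <- function(x, samples = NULL, loci = NULL) {
  si <- seq_len(n_samples(x))
  li <- seq_len(n_loci(x))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples$sample_id)
          else si[samples]
    if (anyNA(si)) stop("unknown sample_id in subset")
  }
  if (!is.null(loci)) {
    li <- if (is.character(loci)) match(loci, x$loci) else li[loci]
    if (anyNA(li)) stop("unknown locus in subset")
  }
  genotype_table(x$samples[si, , drop = FALSE], x$loci[li],
                 x$calls[si, li, , drop = FALSE])
}

#' Row-bind genotype tables sharing the same loci
#' @param ... `genotype_table` objects with identical locus vectors.
#' @return combined `genotype_table`.
#' @export
gt_rbind <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1)
  loci <- xs[[1]]$loci
  for (x in xs) {
    if (!identical(x$loci, loci)) stop("tables must share identical loci")
  }
  samples <- do.call(rbind, lapply(xs, function(x) x$samples))
  n <- nrow(samples)
  calls <- array(NA_integer_, dim = c(n, length(loci), 2))
  at <- 0L
  for (x in xs) {
    idx <- at + seq_len(n_samples(x))
    calls[idx, , ] <- x$calls
    at <- at + n_samples(x)
  }
  genotype_table(samples, loci, calls)
}

#' Count non-missing locus calls per sample
#' @param x a `genotype_table`.
#' @return named integer vector, one entry per sample.
#' @export
loci_typed <- function(x) {
  cnt <- rowSums(!is.na(x$calls[, , 1, drop = FALSE]))
  stats::setNames(as.integer(cnt), x$samples$sample_id)
}

# TRUE where the stored pair is heterozygous, NA where missing
is_het_matrix <- function(x) {
  a <- x$calls[, , 1, drop = TRUE]
  b <- x$calls[, , 2, drop = TRUE]
  if (is.null(dim(a))) { # single sample or locus collapses
    a <- matrix(a, n_samples(x), n_loci(x))
    b <- matrix(b, n_samples(x), n_loci(x))
  }
  a != b
}
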