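#' Maximum-likelihood null-allele frequency at one locus
#'
#' Fits, by EM, the standard one-null-allele model under Hardy-Weinberg
#' proportions: visible alleles `i` at frequencies `p_i` plus a null allele
#' at frequency `r` (`sum p_i + r = 1`). A visible homozygote `i/i` has
#' probability `p_i^2 + 2 p_i r` (true homozygote or null heterozygote), a
#' visible heterozygote `i/j` has `2 p_i p_j`, and a blank (no
#' amplification) has probability `beta + (1 - beta) r^2`, where `beta` is
#' a non-genetic per-locus failure rate. By default `beta` is estimated
#' jointly (so technical dropouts do not masquerade as null homozygotes and
#' `r` is driven by the homozygote excess); fixing `beta = 0` gives the
#' pure blank-scored variant in which every blank is evidence for nulls.
#'
#' @param counts a [genotype_counts()] / [as_genotype_counts()] object.
#' @param n_blank number of blank (missing) calls at the locus among the
#'   scored samples.
#' @param beta non-genetic failure probability; a number to fix it, or
#'   `NULL` (default) to estimate it by ML.
#' @param blanks_scored if `TRUE` (default) blanks enter the likelihood as
#'   their own class; if `FALSE` blanks are ignored and the likelihood is
#'   renormalised over the visible classes (truncated multinomial; the EM
#'   imputes the expected blank count).
#' @param max_iter,tol EM iteration cap and convergence tolerance on `r`.
#' @return list with `naf` (the MLE of `r`), `freqs` (visible-allele MLEs),
#'   `beta` (fixed or estimated), `n_iter`, `converged`.
#' @export
null_allele_ml <- function(counts, n_blank = 0, beta = NULL,
                           blanks_scored = TRUE, max_iter = 5000,
                           tol = 1e-10) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (length(counts$alleles) < 1 || counts$n < 1) {
    stop("no genotype data for null-allele estimation")
  }
  if (!blanks_scored) n_blank <- 0
  if (is.null(beta)) {
    # joint ML over (p, r, beta): with beta free the blank-class
    # probability is a free parameter, so r and p maximise the truncated
    # (visible-class) likelihood and beta absorbs the remaining blanks.
    fit <- null_em(counts, n_blank = 0, beta = 0, truncated = TRUE,
                   max_iter = max_iter, tol = tol)
    n_tot <- counts$n + n_blank
    qhat <- if (n_tot > 0) n_blank / n_tot else 0
    beta_hat <- (qhat - fit$naf^2) / (1 - fit$naf^2)
    if (beta_hat >= 0 || n_blank == 0) {
      fit$beta <- max(0, beta_hat)
      return(fit)
    }
    # fewer blanks than r^2 predicts: boundary beta = 0, blanks informative
    fit <- null_em(counts, n_blank = n_blank, beta = 0, truncated = FALSE,
                   max_iter = max_iter, tol = tol)
    fit$beta <- 0
    return(fit)
  }
  fit <- null_em(counts, n_blank = n_blank, beta = beta,
                 truncated = !blanks_scored, max_iter = max_iter, tol = tol)
  fit$beta <- beta
  fit
}

# EM core; truncated = TRUE imputes the expected blank count each step
null_em <- function(counts, n_blank, beta, truncated, max_iter, tol) {
  k <- length(counts$alleles)
  prs <- strsplit(names(counts$counts), "/", fixed = TRUE)
  ii <- vapply(prs, function(p) match(as.integer(p[1]), counts$alleles), 0L)
  jj <- vapply(prs, function(p) match(as.integer(p[2]), counts$alleles), 0L)
  cnt <- as.numeric(counts$counts)
  hom <- ii == jj
  n_vis <- sum(cnt)

  m <- numeric(k)
  for (t in seq_along(cnt)) {
    m[ii[t]] <- m[ii[t]] + cnt[t]
    m[jj[t]] <- m[jj[t]] + cnt[t]
  }
  p <- m / sum(m) * 0.95
  r <- 0.05
  r_old <- Inf; it <- 0L
  while (it < max_iter && abs(r - r_old) > tol) {
    it <- it + 1L
    r_old <- r
    blanks_eff <- n_blank
    if (truncated) {
      pr_blank <- r^2
      blanks_eff <- if (pr_blank < 1 - 1e-12) n_vis * pr_blank / (1 - pr_blank)
                    else 0
    }
    null_blanks <- blanks_eff
    if (beta > 0) {
      pr_nn <- (1 - beta) * r^2
      denom <- beta + pr_nn
      null_blanks <- if (denom > 0) blanks_eff * pr_nn / denom else 0
    }
    a <- numeric(k); a_null <- 2 * null_blanks
    for (t in seq_along(cnt)) {
      if (hom[t]) {
        i <- ii[t]
        denom <- p[i]^2 + 2 * p[i] * r
        w_null <- if (denom > 0) 2 * p[i] * r / denom else 0
        a[i] <- a[i] + cnt[t] * (2 - w_null)
        a_null <- a_null + cnt[t] * w_null
      } else {
        a[ii[t]] <- a[ii[t]] + cnt[t]
        a[jj[t]] <- a[jj[t]] + cnt[t]
      }
    }
    tot <- sum(a) + a_null
    p <- a / tot
    r <- a_null / tot
  }
  list(naf = r, freqs = stats::setNames(p, counts$alleles),
       n_iter = it, converged = abs(r - r_old) <= tol)
}
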