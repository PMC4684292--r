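#' Per-sex diversity and null-allele statistics for one locus
#'
#' Recomputes the locus statistics separately on the male-only and
#' female-only sub-tables. In birds males are the homogametic sex (ZZ), so
#' a Z-linked microsatellite behaves as an ordinary diploid locus in males;
#' females (ZW) are hemizygous and — because fragment analysis records
#' their single allele as a homozygous call — show observed heterozygosity
#' exactly 0 while expected heterozygosity stays at the allele-frequency
#' level. That contrast is the sex-linkage signature this module screens
#' for.
#'
#' @param table a [genotype_table()] whose `samples$sex` holds
#'   `"male"`/`"female"` (or pass `sexes`).
#' @param locus locus name or index.
#' @param sexes optional named character vector overriding the table's sex
#'   column.
#' @param heterogametic which sex is hemizygous on the shared sex
#'   chromosome: `"female"` for ZW birds (default), `"male"` for XY
#'   systems.
#' @return a `sex_split_stats` row (data.frame): per-sex `h_exp`, `h_obs`,
#'   `naf`, pooled NAF, sample sizes, and an (unflagged) `flag` column of
#'   `"undetermined"` when a sex has fewer than 2 typed individuals.
#' @export
sex_split_stats <- function(table, locus, sexes = NULL,
                            heterogametic = c("female", "male")) {
  heterogametic <- match.arg(heterogametic)
  l <- locus_index(table, locus)
  sx <- if (is.null(sexes)) table$samples$sex
        else sexes[table$samples$sample_id]
  one_sex <- function(which_sex) {
    idx <- which(sx == which_sex)
    sub <- gt_subset(table, samples = idx)
    typed <- sum(!is.na(sub$calls[, l, 1]))
    if (typed < 2) {
      return(list(h_exp = NA_real_, h_obs = NA_real_, naf = NA_real_,
                  n_typed = typed))
    }
    hz <- heterozygosities(sub, l)
    nb <- sum(is.na(sub$calls[, l, 1]))
    naf <- null_allele_ml(genotype_counts(sub, l), n_blank = nb)$naf
    list(h_exp = hz$h_exp, h_obs = hz$h_obs, naf = naf, n_typed = typed)
  }
  males <- one_sex("male")
  females <- one_sex("female")
  pooled_idx <- which(sx %in% c("male", "female"))
  pooled_naf <- if (length(pooled_idx) >= 2) {
    sub <- gt_subset(table, samples = pooled_idx)
    nb <- sum(is.na(sub$calls[, l, 1]))
    null_allele_ml(genotype_counts(sub, l), n_blank = nb)$naf
  } else NA_real_
  undet <- males$n_typed < 2 || females$n_typed < 2
  out <- data.frame(
    locus = table$loci[l],
    male_h_exp = males$h_exp, male_h_obs = males$h_obs, male_naf = males$naf,
    female_h_exp = females$h_exp, female_h_obs = females$h_obs,
    female_naf = females$naf,
    pooled_naf = pooled_naf,
    n_males = males$n_typed, n_females = females$n_typed,
    heterogametic = heterogametic,
    flag = if (undet) "undetermined" else NA_character_,
    rationale = if (undet) "fewer than 2 typed individuals in a sex"
                else NA_character_,
    stringsAsFactors = FALSE)
  class(out) <- c("sex_split_stats", class(out))
  out
}

#' Flag a locus as Z-linked from its sex-split statistics
#'
#' Decision rule formalising the diagnostic pattern: a locus is flagged
#' `z_linked` iff, in the heterogametic sex, observed heterozygosity is
#' (near) zero while expected heterozygosity is substantial, and the
#' homogametic sex looks like an ordinary diploid locus (null-allele
#' frequency below `naf_max`). The `h_min` floor prevents near-monomorphic
#' loci, which trivially have zero observed heterozygosity, from being
#' flagged without evidence.
#'
#' @param stats a `sex_split_stats` row from [sex_split_stats()].
#' @param eps tolerance on the heterogametic sex's observed heterozygosity
#'   (default `1e-9`: exact scoring; raise for noisy data).
#' @param h_min minimum heterogametic-sex expected heterozygosity.
#' @param naf_max maximum homogametic-sex null-allele frequency.
#' @return the row with `flag` set to `"z_linked"`, `"autosomal"` or
#'   `"undetermined"` and `rationale` describing which criteria fired.
#' @export
flag_z_linked <- function(stats, eps = 1e-9, h_min = 0.3, naf_max = 0.1) {
  stopifnot(inherits(stats, "sex_split_stats"))
  if (!is.na(stats$flag) && stats$flag == "undetermined") return(stats)
  hetero_obs <- if (stats$heterogametic == "female") stats$female_h_obs
                else stats$male_h_obs
  hetero_exp <- if (stats$heterogametic == "female") stats$female_h_exp
                else stats$male_h_exp
  homo_naf <- if (stats$heterogametic == "female") stats$male_naf
              else stats$female_naf
  crit <- c(
    hetero_obs_zero = isTRUE(hetero_obs <= eps),
    hetero_exp_high = isTRUE(hetero_exp >= h_min),
    homo_naf_low = isTRUE(homo_naf <= naf_max))
  if (all(crit)) {
    stats$flag <- "z_linked"
    stats$rationale <- sprintf(
      "%s H_O = %.3g <= %g with H_E = %.3g >= %g; %s NAF = %.3g <= %g",
      stats$heterogametic, hetero_obs, eps, hetero_exp, h_min,
      setdiff(c("male", "female"), stats$heterogametic), homo_naf, naf_max)
  } else {
    stats$flag <- "autosomal"
    stats$rationale <- paste("criteria not met:",
                             paste(names(crit)[!crit], collapse = ", "))
    if (all(crit[c("hetero_obs_zero")]) && !crit[["hetero_exp_high"]]) {
      stats$rationale <- paste(stats$rationale,
                               "(near-monomorphic locus, no power)")
    }
  }
  stats
}

#' Screen every locus for sex linkage
#'
#' Applies [sex_split_stats()] + [flag_z_linked()] across all loci and
#' returns the recommended exclusion set, which feeds the "without
#' sex-linked loci" average of [summarize_population()] and is dropped
#' from clustering input by the pipeline. Requires sex metadata: sex
#' linkage is undetectable without separate analysis of males and females.
#'
#' @inheritParams sex_split_stats
#' @param ... threshold arguments passed to [flag_z_linked()].
#' @return list with `report` (data.frame, one row per locus) and
#'   `exclude` (character vector of flagged locus names).
#' @export
screen_all_loci <- function(table, sexes = NULL,
                            heterogametic = c("female", "male"), ...) {
  heterogametic <- match.arg(heterogametic)
  sx <- if (is.null(sexes)) table$samples$sex
        else sexes[table$samples$sample_id]
  if (!any(sx %in% c("male", "female"))) {
    stop(paste("no sex metadata: sex linkage cannot be detected without",
               "separate analysis of males and females"))
  }
  rows <- lapply(seq_len(n_loci(table)), function(l) {
    flag_z_linked(sex_split_stats(table, l, sexes = sexes,
                                  heterogametic = heterogametic), ...)
  })
  report <- do.call(rbind, rows)
  list(report = report,
       exclude = report$locus[report$flag == "z_linked"])
}
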