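#' Configuration for the synthetic breeding-population simulators
#'
#' Bundles every parameter the simulators need, with defaults set to the
#' conditions of the study the package models: sire variance 0.03947 on the
#' log-hazard scale, roughly 22% censoring under a ~0.8 per-year baseline
#' survival with staggered cohort entry, and gait traits with heritabilities
#' and repeatabilities in the published 0.11-0.44 / 0.45-0.74 ranges.
#'
#' @param seed Master integer seed; fully determines every simulator's output.
#' @param n_founders Number of pedigree founders (split evenly between sexes).
#' @param n_generations Number of descendant generations to breed.
#' @param progeny_per_sire Progeny produced per mating sire per generation.
#' @param n_snps Number of simulated SNPs.
#' @param maf_range Range of founder minor-allele frequencies, in (0, 0.5].
#' @param true_sire_variance True sire variance on the log-hazard scale.
#' @param baseline_survival Per-career-year baseline survival probabilities
#'   \eqn{\alpha_j \in (0,1)}; recycled for careers longer than its length.
#' @param entry_years Calendar years over which horses enter competition.
#' @param censor_year Calendar year at which still-active careers are censored.
#' @param gait_h2 Narrow-sense heritability of the simulated gait trait.
#' @param gait_repeatability Repeatability (genetic + permanent environment
#'   fraction of phenotypic variance); must be at least `gait_h2`.
#' @param gait_phenotypic_var Phenotypic variance of the gait trait.
#' @param true_rg True genetic correlation between the gait trait and the
#'   longevity sire effect (risk scale: negative favours longevity).
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_founders = 20, n_generations = 2)
#' cfg$true_sire_variance
sim_config <- function(seed = 1L,
                       n_founders = 100L,
                       n_generations = 2L,
                       progeny_per_sire = 10L,
                       n_snps = 1000L,
                       maf_range = c(0.05, 0.5),
                       true_sire_variance = 0.03947,
                       baseline_survival = 0.8,
                       entry_years = 2002:2018,
                       censor_year = 2018L,
                       gait_h2 = 0.44,
                       gait_repeatability = 0.73,
                       gait_phenotypic_var = 1,
                       true_rg = -0.38) {
  if (n_founders < 2) abort("`n_founders` must be at least 2.")
  if (n_generations < 0) abort("`n_generations` must be non-negative.")
  if (any(maf_range <= 0) || any(maf_range > 0.5) || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair inside (0, 0.5].")
  }
  if (true_sire_variance < 0) abort("`true_sire_variance` must be >= 0.")
  if (any(baseline_survival <= 0) || any(baseline_survival >= 1)) {
    abort("`baseline_survival` probabilities must lie strictly in (0, 1).")
  }
  if (gait_h2 < 0 || gait_h2 > 1) abort("`gait_h2` must lie in [0, 1].")
  if (gait_repeatability < gait_h2) {
    abort("`gait_repeatability` must be >= `gait_h2` (permanent environment variance cannot be negative).")
  }
  if (gait_repeatability > 1) abort("`gait_repeatability` must be <= 1.")
  if (abs(true_rg) > 1) abort("`true_rg` must lie in [-1, 1].")
  structure(
    list(
      seed = as.integer(seed),
      n_founders = as.integer(n_founders),
      n_generations = as.integer(n_generations),
      progeny_per_sire = as.integer(progeny_per_sire),
      n_snps = as.integer(n_snps),
      maf_range = as.numeric(maf_range),
      true_sire_variance = true_sire_variance,
      baseline_survival = as.numeric(baseline_survival),
      entry_years = as.integer(entry_years),
      censor_year = as.integer(censor_year),
      gait_h2 = gait_h2,
      gait_repeatability = gait_repeatability,
      gait_phenotypic_var = gait_phenotypic_var,
      true_rg = true_rg
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d founders, %d generations, %d progeny/sire, %d SNPs\n",
              x$seed, x$n_founders, x$n_generations, x$progeny_per_sire, x$n_snps))
  cat(sprintf("  sire variance %.5f | baseline survival %s | censor year %d\n",
              x$true_sire_variance,
              paste(format(x$baseline_survival), collapse = ","), x$censor_year))
  cat(sprintf("  gait h2 %.2f, repeatability %.2f, r_g %.2f\n",
              x$gait_h2, x$gait_repeatability, x$true_rg))
  invisible(x)
}
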