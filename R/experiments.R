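# End-to-end parameter-recovery experiments: simulate at the study's
# parameter values, run the estimation stage, report the recovered values.
# These are the workhorses of the reproduction checks in
# scripts/acceptance.R and the acceptance tests.

#' Sire-variance recovery under the discrete-time hazard model
#'
#' Simulates unrelated sires with fixed progeny-group size under the
#' discrete hazard model at the configured sire variance and roughly 22%
#' censoring, fits the Laplace-marginal estimator, and repeats.
#'
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param n_sires Number of sires (the study recovery uses 1,000).
#' @param progeny_per_sire Progeny per sire (30).
#' @param replicates Number of simulation replicates.
#' @param sigma_s2 True sire variance.
#' @return Tibble with one row per replicate: `sigma_hat`, `censored`,
#'   `h2`, `converged`.
#' @export
experiment_survival_recovery <- function(seed = 1, n_sires = 1000L,
                                         progeny_per_sire = 30L,
                                         replicates = 20L,
                                         sigma_s2 = 0.03947) {
  purrr::map_dfr(seq_len(replicates), function(r) {
    cfg <- sim_config(seed = seed + r, n_founders = 2L * n_sires,
                      n_generations = 1L,
                      progeny_per_sire = progeny_per_sire,
                      true_sire_variance = sigma_s2)
    ped <- simulate_pedigree(cfg)
    tr <- simulate_breeding_values(ped, cfg)
    ca <- simulate_careers(ped, tr, cfg)
    fit <- fit_survival(ca)
    tibble(replicate = r, sigma_hat = fit$sigma_s2,
           censored = 1 - fit$p_uncensored, h2 = fit$h2,
           converged = fit$converged)
  })
}

#' Bivariate genetic-correlation recovery
#'
#' Simulates the joint design of the study: sires carrying weighted
#' longevity pseudo-phenotypes (reliabilities spread 0.40-0.97), a subset of
#' them with gait-recorded progeny (two recordings each), an optional
#' reduced SNP panel combined into a single-step H, and constrained REML
#' with the longevity components fixed.
#'
#' @param seed Master seed; replicate r uses `seed + 10 * r`.
#' @param h2,repeatability,rg True gait-trait parameters.
#' @param replicates Simulation replicates (estimates are averaged over
#'   replicates when reporting a recovered value).
#' @param n_sires Pseudo-phenotyped sires.
#' @param n_families Sires with gait-recorded progeny.
#' @param progeny_per_family Gait horses per such sire.
#' @param n_genotyped Animals on the reduced SNP panel (0 = pedigree only).
#' @param n_snps Panel size.
#' @return Tibble with one row per replicate: estimates, the first
#'   replicate's standard errors, convergence status.
#' @export
experiment_bitrait_recovery <- function(seed = 1, h2, repeatability, rg,
                                        replicates = 6L,
                                        n_sires = 2000L, n_families = 300L,
                                        progeny_per_family = 5L,
                                        n_genotyped = 450L, n_snps = 5000L) {
  purrr::map_dfr(seq_len(replicates), function(r) {
    cfg <- sim_config(seed = seed + 10L * r, gait_h2 = h2,
                      gait_repeatability = repeatability, true_rg = rg,
                      n_snps = n_snps)
    n_gait <- n_families * progeny_per_family
    ped <- as_pedigree(tibble(
      id = seq_len(n_sires + n_gait),
      sire = c(rep(NA, n_sires), rep(seq_len(n_families),
                                     each = progeny_per_family)),
      dam = NA,
      sex = c(rep("M", n_sires), rep("F", n_gait)),
      birth_year = c(rep(1990L, n_sires), rep(2011L, n_gait)),
      generation = c(rep(0L, n_sires), rep(1L, n_gait))))
    gait_ids <- ped$id[!is.na(ped$sire)]
    # with a SNP panel in the analysis, the truth must be marker-based so
    # that realized genomic relationships describe the breeding values
    gt <- if (n_genotyped > 0) simulate_genotypes(ped, cfg)
    tr <- if (n_genotyped > 0) {
      simulate_breeding_values_from_markers(gt, cfg)
    } else {
      simulate_breeding_values(ped, cfg)
    }
    gait <- simulate_gait_records(ped, tr, cfg, horses = gait_ids)
    spec <- bitrait_spec(sigma_u_star2 = cfg$true_sire_variance)
    pseudo <- simulate_pseudo_phenotypes(tr, cfg, sires = seq_len(n_sires),
                                         spec = spec)
    Ainv <- build_A_inverse(ped)
    Hinv <- Ainv
    if (n_genotyped > 0) {
      pick <- with_stream(cfg$seed, "panel", {
        c(sample(as.character(gait_ids), round(2 / 3 * n_genotyped)),
          sample(as.character(seq_len(n_sires)), round(1 / 3 * n_genotyped)))
      })
      G <- build_G(genotype_matrix(gt$geno[pick, ], gt$map))
      Hinv <- build_H_inverse(Ainv, G, pick, ped)
    }
    fit <- reml_bitrait(gait, pseudo, Hinv, spec, compute_se = (r == 1L))
    d <- fit$derived
    grab <- function(p, col) {
      v <- d[[col]][d$parameter == p]
      if (length(v)) v else NA_real_
    }
    tibble(replicate = r,
           h2_hat = grab("h2", "estimate"), h2_se = grab("h2", "se"),
           repeatability_hat = grab("repeatability", "estimate"),
           repeatability_se = grab("repeatability", "se"),
           rg_hat = grab("r_g", "estimate"), rg_se = grab("r_g", "se"),
           converged = fit$converged, message = fit$message)
  })
}

#' Repeated-records heritability and repeatability recovery
#'
#' Simulates horses with two gait recordings each in paternal half-sib
#' families and estimates the variance components by the same REML stage,
#' single-trait (pedigree relationship only).
#'
#' @param seed Master seed; replicate r uses `seed + 100 * r`.
#' @param h2,repeatability True parameter values.
#' @param replicates Simulation replicates.
#' @param n_horses Recorded horses (two records each).
#' @param n_sires Sires of those horses.
#' @return Tibble per replicate: `h2_hat`, `repeatability_hat`, first
#'   replicate's SEs, convergence.
#' @export
experiment_repeated_records <- function(seed = 1, h2 = 0.44,
                                        repeatability = 0.73,
                                        replicates = 4L,
                                        n_horses = 2000L, n_sires = 200L) {
  progeny <- ceiling(n_horses / n_sires)
  purrr::map_dfr(seq_len(replicates), function(r) {
    cfg <- sim_config(seed = seed + 100L * r, gait_h2 = h2,
                      gait_repeatability = repeatability)
    ped <- as_pedigree(tibble(
      id = seq_len(n_sires + n_sires * progeny),
      sire = c(rep(NA, n_sires), rep(seq_len(n_sires), each = progeny)),
      dam = NA,
      sex = c(rep("M", n_sires), rep("F", n_sires * progeny)),
      birth_year = c(rep(1990L, n_sires), rep(2011L, n_sires * progeny)),
      generation = c(rep(0L, n_sires), rep(1L, n_sires * progeny))))
    tr <- simulate_breeding_values(ped, cfg)
    horses <- ped$id[!is.na(ped$sire)][seq_len(n_horses)]
    gait <- simulate_gait_records(ped, tr, cfg, horses = horses)
    fit <- reml_bitrait(gait, longevity = NULL, Hinv = build_A_inverse(ped),
                        spec = bitrait_spec(), compute_se = (r == 1L))
    d <- fit$derived
    grab <- function(p, col) {
      v <- d[[col]][d$parameter == p]
      if (length(v)) v else NA_real_
    }
    tibble(replicate = r,
           h2_hat = grab("h2", "estimate"), h2_se = grab("h2", "se"),
           repeatability_hat = grab("repeatability", "estimate"),
           repeatability_se = grab("repeatability", "se"),
           converged = fit$converged)
  })
}
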