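#' Simulate competition careers under the discrete-time hazard model
#'
#' Each horse enters competition in a calendar year drawn from
#' `cfg$entry_years` and, in career year \eqn{j}, survives with probability
#' \eqn{\alpha_j^{\exp(\eta)}} where \eqn{\eta = z'\beta + u_s + \tfrac12
#' u_{mgs}} combines any configured fixed effects with the sire and maternal
#' grandsire transmitting abilities. Careers still active at
#' `cfg$censor_year` are censored, which with the default staggered entry
#' yields roughly 22% censoring.
#'
#' @param ped A pedigree.
#' @param truth Truth tibble from [simulate_breeding_values()] (column
#'   `bv_longevity` on the sire-effect scale).
#' @param cfg A [sim_config()].
#' @param horses Ids of horses given careers; default: every animal with a
#'   known sire.
#' @param gender_effects Named log-hazard offsets for the three genders
#'   (default all zero).
#' @return Tibble of one row per horse-year: `horse`, `year` (career index),
#'   `calendar_year`, `gender`, `region`, `birth_month`, `age_first`,
#'   `points` (log-scale, standard-normal), `sire`, `mgs`, `status`
#'   (`event`, `censored` or `continued`).
#' @export
simulate_careers <- function(ped, truth, cfg, horses = NULL,
                             gender_effects = c(F = 0, M = 0, G = 0)) {
  ped <- as_pedigree(ped)
  mgs_view <- ped_mgs_view(ped)
  horses <- horses %||% ped$id[!is.na(ped$sire)]
  if (!all(as.character(horses) %in% as.character(ped$id))) {
    abort("some career horses are absent from the pedigree")
  }
  u <- setNames(truth$bv_longevity, as.character(truth$id))
  miss <- setdiff(as.character(stats::na.omit(ped$sire[match(horses, ped$id)])),
                  names(u))
  if (length(miss)) abort("truth table lacks breeding values for some sires")
  with_stream(cfg$seed, "careers", {
    hrow <- match(as.character(horses), as.character(mgs_view$id))
    sire <- mgs_view$sire[hrow]
    mgs <- mgs_view$mgs[hrow]
    nh <- length(horses)
    gender <- sample(names(gender_effects), nh, replace = TRUE,
                     prob = c(0.49, 0.16, 0.35))
    region <- sample.int(13L, nh, replace = TRUE)
    birth_month <- sample.int(8L, nh, replace = TRUE)
    age_first <- sample.int(6L, nh, replace = TRUE,
                            prob = c(.45, .3, .12, .07, .04, .02))
    entry <- cfg$entry_years[sample.int(length(cfg$entry_years), nh,
                                        replace = TRUE)]
    eta <- unname(gender_effects[gender]) +
      ifelse(is.na(sire), 0, u[as.character(sire)]) +
      0.5 * ifelse(is.na(mgs), 0, u[as.character(mgs)])
    max_year <- pmax(cfg$censor_year - entry + 1L, 1L)
    M <- max(max_year)
    alpha <- cfg$baseline_survival[pmin(seq_len(M), length(cfg$baseline_survival))]
    # year-by-year Bernoulli survival, all horses at once
    surv <- matrix(runif(nh * M), nh, M) <=
      outer(exp(eta), -log(alpha), function(e, m) exp(-m * e))
    died <- !surv
    has_death <- rowSums(died) > 0
    first_death <- ifelse(has_death, max.col(died, ties.method = "first"), Inf)
    lifetime <- as.integer(pmin(first_death, max_year))
    censored <- first_death > max_year
    idx <- rep(seq_len(nh), lifetime)
    j <- sequence(lifetime)
    last <- j == lifetime[idx]
    tibble(
      horse = horses[idx],
      year = j,
      calendar_year = entry[idx] + j - 1L,
      gender = gender[idx],
      region = region[idx],
      birth_month = birth_month[idx],
      age_first = age_first[idx],
      points = rnorm(length(idx)),
      sire = sire[idx],
      mgs = mgs[idx],
      status = ifelse(!last, "continued",
                      ifelse(censored[idx], "censored", "event"))
    )
  })
}
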