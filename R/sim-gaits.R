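#' Simulate repeated gait-score records with known variance components
#'
#' Generates one gait principal-component-style trait: each horse receives a
#' genetic value (from the truth table, correlated with longevity by
#' `cfg$true_rg`), a permanent-environment deviation with variance
#' \eqn{(rep - h^2)\sigma_P^2}, and per-recording residuals with variance
#' \eqn{(1 - rep)\sigma_P^2}. Trot/canter-style traits get two recordings
#' (working and medium); walk-style traits one.
#'
#' @param ped A pedigree.
#' @param truth Truth tibble from [simulate_breeding_values()].
#' @param cfg A [sim_config()].
#' @param horses Ids of recorded horses; default: the youngest generation.
#' @param n_recordings 2 for trot/canter-style traits, 1 for walk-style.
#' @param gait Label stored in the output (`"trot"` by default).
#' @param event_sd Standard deviation of the random competition-event fixed
#'   effects (26 events); 0 removes them.
#' @return Tibble with columns `horse`, `event_id`, `gait`, `recording_type`,
#'   `trait`, `value`, `velocity`, `height`, `gender`, `age`.
#' @export
simulate_gait_records <- function(ped, truth, cfg, horses = NULL,
                                  n_recordings = 2L, gait = "trot",
                                  event_sd = 0.3) {
  ped <- as_pedigree(ped)
  horses <- horses %||% ped$id[ped$generation == max(ped$generation)]
  g <- setNames(truth$bv_gait, as.character(truth$id))
  if (!all(as.character(horses) %in% names(g))) {
    abort("truth table lacks gait breeding values for some horses")
  }
  sP <- cfg$gait_phenotypic_var
  s_pe <- (cfg$gait_repeatability - cfg$gait_h2) * sP
  s_e <- (1 - cfg$gait_repeatability) * sP
  with_stream(cfg$seed, "gait-records", {
    nh <- length(horses)
    event_eff <- rnorm(26L, 0, event_sd)
    event_id <- sample.int(26L, nh, replace = TRUE)
    gender <- sample(c("F", "M", "G"), nh, replace = TRUE, prob = c(.5, .15, .35))
    age <- sample(c(4L, 5L), nh, replace = TRUE, prob = c(.42, .58))
    velocity <- rnorm(nh, 3.5, 0.3)
    height <- rnorm(nh, 166.7, 4.2)
    pe <- rnorm(nh, 0, sqrt(s_pe))
    rec <- rep(seq_len(n_recordings), times = nh)
    idx <- rep(seq_len(nh), each = n_recordings)
    value <- event_eff[event_id[idx]] +
      g[as.character(horses[idx])] + pe[idx] +
      rnorm(length(idx), 0, sqrt(s_e))
    tibble(
      horse = horses[idx],
      event_id = event_id[idx],
      gait = gait,
      recording_type = c("working", "medium")[rec],
      trait = paste0(gait, "_pc"),
      value = unname(value),
      velocity = velocity[idx],
      height = height[idx],
      gender = gender[idx],
      age = age[idx]
    )
  })
}

#' Simulate raw multi-variable gait measurements
#'
#' Generates the eight accelerometric variables (seven for canter: no
#' symmetry) with a latent factor structure plus per-horse effects, suitable
#' for exercising the horse-effect adjustment and per-gait PCA. Variables
#' load on a small number of latent axes so that three components capture
#' most of the variance, as observed on real accelerometer panels.
#'
#' @param n_horses Number of horses.
#' @param gait `"walk"`, `"trot"` or `"canter"`.
#' @param seed Integer seed.
#' @param n_factors Number of latent axes.
#' @return Tibble in long format: `horse`, `event_id`, `gait`,
#'   `recording_type`, `variable`, `value`, `velocity`, `height`, `gender`,
#'   `age`.
#' @export
simulate_gait_measurements <- function(n_horses = 300L, gait = "trot",
                                       seed = 1L, n_factors = 3L) {
  vars <- gait_variables(gait)
  nv <- length(vars)
  with_stream(seed, paste0("gait-measurements-", gait), {
    load <- matrix(rnorm(nv * n_factors, 0, 1), nv, n_factors)
    fac <- matrix(rnorm(n_horses * n_factors), n_horses, n_factors)
    horse_eff <- fac %*% Matrix::t(load) +
      matrix(rnorm(n_horses * nv, 0, 0.4), n_horses, nv)
    event_id <- sample.int(26L, n_horses, replace = TRUE)
    event_eff <- rnorm(26L)
    gender <- sample(c("F", "M", "G"), n_horses, replace = TRUE)
    age <- sample(c(4L, 5L), n_horses, replace = TRUE)
    velocity <- rnorm(n_horses, 3.5, 0.3)
    height <- rnorm(n_horses, 166.7, 4.2)
    n_rec <- if (gait == "walk") 1L else 2L
    idx <- rep(seq_len(n_horses), each = n_rec * nv)
    rec <- rep(rep(seq_len(n_rec), each = nv), times = n_horses)
    v <- rep(rep(seq_len(nv), times = n_rec), times = n_horses)
    value <- horse_eff[cbind(idx, v)] + 0.8 * event_eff[event_id[idx]] +
      0.3 * (velocity[idx] - 3.5) * (vars[v] != "velocity") +
      rnorm(length(idx), 0, 0.5)
    tibble(
      horse = idx, event_id = event_id[idx], gait = gait,
      recording_type = c("working", "medium")[rec],
      variable = vars[v], value = value,
      velocity = velocity[idx], height = height[idx],
      gender = gender[idx], age = age[idx]
    )
  })
}

# canonical accelerometric variable sets; canter has no symmetry
gait_variables <- function(gait) {
  base <- c("velocity", "stride_frequency", "regularity", "symmetry",
            "dorsoventral_displacement", "dorsoventral_activity",
            "longitudinal_activity", "lateral_activity")
  if (gait == "canter") setdiff(base, "symmetry") else base
}
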