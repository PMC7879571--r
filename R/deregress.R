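# Deregression of survival-model EBVs into weighted pseudo-phenotypes:
# reliability, pruning of relative-derived information, weights, deregressed
# values, retention filtering.

#' Reliability of an EBV from its prediction-error variance
#'
#' \eqn{R = 1 - t/\sigma_u^2} with `t` the prediction-error variance.
#' Numerical overshoot (`t` slightly above the genetic variance) is clamped
#' to 0 with a warning.
#'
#' @param t Prediction-error variance(s).
#' @param sigma_u2 Genetic variance.
#' @return Reliability in `[0, 1]`.
#' @export
reliability <- function(t, sigma_u2) {
  if (sigma_u2 <= 0) abort("`sigma_u2` must be positive")
  r <- 1 - t / sigma_u2
  if (any(r < -1e-6, na.rm = TRUE)) {
    warn("prediction-error variance exceeds the genetic variance; reliability clamped to 0")
  }
  pmin(pmax(r, 0), 1)
}

#' Remove relative-derived information from reliabilities
#'
#' Expresses each reliability as an information content
#' \eqn{T = \lambda R/(1-R)} (effective own-record count with
#' \eqn{\lambda = \sigma_\epsilon^2/\sigma_u^2}), subtracts the
#' parent-average information implied by the *cleaned* parental
#' reliabilities (\eqn{R_{PA} = (R'_{sire} + R'_{dam})/4}, a missing parent
#' contributing 0), and iterates the downward pedigree pass to a fixed
#' point. The result \eqn{R' = T_{own}/(T_{own} + \lambda)} reflects progeny
#' and own information only. Pruning never increases a reliability and an
#' animal unrelated to all others is a fixed point.
#'
#' @param records Tibble with columns `id` and `R`.
#' @param ped Pedigree over (at least) the recorded animals. For a
#'   sire/MGS evaluation, pass the stallion pedigree (sire and maternal
#'   grandsire as the two parents).
#' @param lambda Variance ratio \eqn{\sigma_\epsilon^2/\sigma_u^2}.
#' @param max_iter,tol Fixed-point controls.
#' @return `records` with columns `Rprime` and `T_own` added.
#' @export
prune_relative_info <- function(records, ped, lambda, max_iter = 100L,
                                tol = 1e-10) {
  check_columns(records, c("id", "R"), "EBV records")
  ped <- as_pedigree(ped)
  pi <- ped_index(ped)
  R <- setNames(rep(0, nrow(ped)), pi$id)
  hasR <- as.character(records$id)
  if (!all(hasR %in% pi$id)) {
    abort("some recorded animals are absent from the pedigree")
  }
  R[hasR] <- pmin(records$R, 1 - 1e-12)
  Tfun <- function(r) lambda * r / (1 - r)
  Rfun <- function(T) T / (T + lambda)
  Ttot <- Tfun(R)
  Town <- Ttot
  s <- pi$sire
  d <- pi$dam
  for (it in seq_len(max_iter)) {
    Rp <- Rfun(Town)
    Rpa <- 0.25 * (ifelse(is.na(s), 0, Rp[ifelse(is.na(s), 1L, s)]) +
                     ifelse(is.na(d), 0, Rp[ifelse(is.na(d), 1L, d)]))
    Town_new <- pmax(Ttot - Tfun(Rpa), 0)
    if (max(abs(Town_new - Town)) < tol * (1 + max(Town))) {
      Town <- Town_new
      break
    }
    Town <- Town_new
  }
  dropped <- Ttot[hasR] > 0 & Town[hasR] == 0
  if (any(dropped)) {
    warn(sprintf("%d animal(s) had purely pedigree-derived reliability (R' = 0)",
                 sum(dropped)))
  }
  records$Rprime <- unname(Rfun(Town[hasR]))
  records$T_own <- unname(Town[hasR])
  records
}

#' Weight implied by a cleaned reliability
#'
#' Solves \eqn{R' = 1 - \frac{1}{\sigma_u^2}\left(w/\sigma_\epsilon^2 +
#' 1/\sigma_u^2\right)^{-1}} for the record weight:
#' \eqn{w = \lambda R'/(1-R')}.
#'
#' @param Rprime Cleaned reliability in `[0, 1)`.
#' @param lambda Variance ratio \eqn{\sigma_\epsilon^2/\sigma_u^2}.
#' @return Weight(s) `w >= 0`, strictly increasing in `Rprime`.
#' @export
weight_from_reliability <- function(Rprime, lambda) {
  if (any(Rprime < 0 | Rprime >= 1)) {
    abort("`Rprime` must lie in [0, 1): a reliability of 1 implies infinite weight")
  }
  lambda * Rprime / (1 - Rprime)
}

#' Deregress EBVs into weighted pseudo-phenotypes
#'
#' \deqn{y^* = D (D^{-1} + \sigma_u^{-2} A^{-1}) \hat u}
#' with \eqn{D = \mathrm{diag}(\sigma_\epsilon^2 / w_i)}. Re-estimating
#' breeding values from \eqn{(y^*, w)} under the simplified model
#' \eqn{y^* = u + \epsilon} reproduces \eqn{\hat u} exactly, for any
#' positive weights. Animals with zero weight carry no own information and
#' are excluded.
#'
#' @param records Tibble with columns `id`, `ebv` and `w` (weights).
#' @param Ainv Relationship inverse over exactly the recorded animals
#'   (dimnames = ids), e.g. `solve(sire_mgs_matrix(ped, ids))`.
#' @param sigma_u2 Genetic variance.
#' @param sigma_e2 Residual variance placing the weights on a scale
#'   (\eqn{\lambda = \sigma_\epsilon^2/\sigma_u^2}).
#' @return Tibble `id`, `y_star`, `w` for the animals with positive weight.
#' @export
deregress <- function(records, Ainv, sigma_u2, sigma_e2) {
  check_columns(records, c("id", "ebv", "w"), "EBV records")
  if (any(records$w <= 0)) {
    warn("animals with zero weight carry no own information; excluded from the system")
    records <- records %>% filter(.data$w > 0)
  }
  if (!nrow(records)) abort("no animal has positive weight")
  ids <- as.character(records$id)
  if (!setequal(ids, rownames(Ainv))) {
    abort("`Ainv` must be the relationship inverse over exactly the weighted animals")
  }
  Ainv <- Ainv[ids, ids, drop = FALSE]
  uhat <- records$ebv
  dinv <- records$w / sigma_e2          # D^-1 diagonal
  y_star <- uhat + as.numeric(Ainv %*% uhat) / (sigma_u2 * dinv)
  tibble(id = records$id, y_star = y_star, w = records$w)
}

#' Retain pseudo-phenotypes with sufficient cleaned reliability
#'
#' @param records Tibble with column `Rprime`.
#' @param threshold Minimum cleaned reliability (study value: 0.40).
#' @return The retained subset, with a `summary` attribute (N, mean, SD,
#'   min, max of each numeric column).
#' @export
retain <- function(records, threshold = 0.40) {
  check_columns(records, "Rprime", "records")
  out <- records %>% filter(.data$Rprime >= threshold)
  num <- names(out)[vapply(out, is.numeric, logical(1))]
  attr(out, "summary") <- purrr::map_dfr(num, function(cn) {
    tibble(variable = cn, n = nrow(out), mean = mean(out[[cn]]),
           sd = sd(out[[cn]]), min = suppressWarnings(min(out[[cn]])),
           max = suppressWarnings(max(out[[cn]])))
  })
  out
}

#' Full deregression pipeline for a survival fit
#'
#' Reliabilities from prediction-error variances, relative-information
#' pruning, weights, deregressed pseudo-phenotypes and retention.
#'
#' @param fit A `survival_fit`.
#' @param ped Stallion pedigree used for pruning and for A.
#' @param h2 Heritability fixing \eqn{\lambda = (1-h^2)/h^2}; default from
#'   the fit.
#' @param threshold Retention threshold on the cleaned reliability.
#' @return Tibble `id`, `ebv`, `R`, `Rprime`, `w`, `y_star` of retained
#'   stallions.
#' @export
deregress_ebv <- function(fit, ped, h2 = fit$h2, threshold = 0.40) {
  stopifnot(inherits(fit, "survival_fit"))
  lambda <- (1 - h2) / h2
  rec <- fit$ebv %>%
    mutate(R = reliability(.data$pev, fit$sigma_s2)) %>%
    select("id", "ebv", "R")
  rec <- prune_relative_info(rec, ped, lambda)
  rec$w <- weight_from_reliability(pmin(rec$Rprime, 1 - 1e-9), lambda)
  sigma_u2 <- fit$sigma_s2
  sigma_e2 <- lambda * sigma_u2
  pos <- rec %>% filter(.data$w > 0)
  A <- sire_mgs_matrix(ped, as.character(pos$id))
  dr <- deregress(pos, solve(A), sigma_u2, sigma_e2)
  out <- pos %>% left_join(dr %>% select("id", "y_star"), by = "id")
  retain(out, threshold)
}
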