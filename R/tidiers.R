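# broom-style accessors for the fitted objects.

#' Tidy a survival fit
#'
#' @param x A `survival_fit`.
#' @param effects `"fixed"` (term/level estimates with risk ratios),
#'   `"baseline"` or `"ranef"` (sire EBVs).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy survival_fit
#' @export
tidy.survival_fit <- function(x, effects = c("fixed", "baseline", "ranef"),
                              ...) {
  effects <- match.arg(effects)
  switch(effects,
         fixed = x$fixed,
         baseline = x$baseline,
         ranef = x$ebv)
}

#' @rdname tidy.survival_fit
#' @method glance survival_fit
#' @export
glance.survival_fit <- function(x, ...) {
  tibble(sigma_s2 = x$sigma_s2, h2 = x$h2, p_uncensored = x$p_uncensored,
         loglik = x$loglik, log_marginal = x$log_marginal,
         n_records = x$n_records, n_horses = x$n_horses,
         n_sires = nrow(x$ebv), converged = x$converged)
}

#' Tidy a bivariate REML fit
#'
#' @param x A `bitrait_reml`.
#' @param type `"derived"` (heritability, repeatability, genetic
#'   correlation) or `"varcomp"` (variance components, with the fixed
#'   longevity components flagged).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bitrait_reml
#' @export
tidy.bitrait_reml <- function(x, type = c("derived", "varcomp"), ...) {
  type <- match.arg(type)
  if (type == "derived") x$derived else x$varcomp
}

#' @rdname tidy.bitrait_reml
#' @method glance bitrait_reml
#' @export
glance.bitrait_reml <- function(x, ...) {
  tibble(loglik = x$loglik, converged = x$converged, message = x$message,
         n_gait = x$n_gait, n_longevity = x$n_longevity,
         n_animals = x$n_animals)
}

#' Table-shaped summary of several gait-trait fits
#'
#' One row per trait: heritability (SE), repeatability (SE), genetic
#' correlation with longevity (SE) and significance stars from Wald tests,
#' mirroring how such genetic-parameter tables are reported.
#'
#' @param fits Named list of `bitrait_reml` objects.
#' @return A tibble with one row per (converged) trait; non-converged fits
#'   keep their row with the declared failure message.
#' @export
parameter_table <- function(fits) {
  stars <- function(p) dplyr::case_when(
    is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
    TRUE ~ "")
  purrr::imap_dfr(fits, function(f, nm) {
    if (!f$converged) {
      return(tibble(trait = nm, h2 = NA_real_, h2_se = NA_real_,
                    repeatability = NA_real_, repeatability_se = NA_real_,
                    r_g = NA_real_, r_g_se = NA_real_, r_g_stars = "",
                    note = f$message))
    }
    d <- f$derived
    g <- function(p, col) {
      v <- d[[col]][d$parameter == p]
      if (length(v)) v else NA_real_
    }
    pw <- 2 * pnorm(-abs(g("r_g", "estimate") / g("r_g", "se")))
    tibble(trait = nm,
           h2 = g("h2", "estimate"), h2_se = g("h2", "se"),
           repeatability = g("repeatability", "estimate"),
           repeatability_se = g("repeatability", "se"),
           r_g = g("r_g", "estimate"), r_g_se = g("r_g", "se"),
           r_g_stars = stars(pw), note = "converged")
  })
}
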