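#' Simulate weighted longevity pseudo-phenotypes for a set of sires
#'
#' Emulates the output of the deregression stage directly: each sire gets a
#' cleaned reliability drawn from a spread like the retained stallions'
#' (0.40-0.97, mean ~0.63), the weight implied by that reliability, and a
#' pseudo-phenotype `y* = u* + e` with `Var(e) = sigma_e_star2 / w`, where
#' `u*` is the sire's true longevity transmitting ability from the truth
#' table.
#'
#' @param truth Truth tibble from [simulate_breeding_values()].
#' @param cfg A [sim_config()].
#' @param sires Ids of the pseudo-phenotyped sires.
#' @param spec A [bitrait_spec()] fixing `sigma_u_star2` / `sigma_e_star2`
#'   (their ratio is the lambda the weights live on).
#' @param reliability_range Range of cleaned reliabilities.
#' @return Tibble `id`, `y_star`, `w`, `Rprime`.
#' @export
simulate_pseudo_phenotypes <- function(truth, cfg, sires,
                                       spec = bitrait_spec(
                                         sigma_u_star2 = cfg$true_sire_variance),
                                       reliability_range = c(0.40, 0.97)) {
  u <- setNames(truth$bv_longevity, as.character(truth$id))
  if (!all(as.character(sires) %in% names(u))) {
    abort("truth table lacks longevity values for some sires")
  }
  lambda <- spec$sigma_e_star2 / spec$sigma_u_star2
  with_stream(cfg$seed, "pseudo-phenotypes", {
    ns <- length(sires)
    Rp <- reliability_range[1] +
      diff(reliability_range) * rbeta(ns, 2, 3)
    w <- weight_from_reliability(Rp, lambda)
    y <- u[as.character(sires)] + rnorm(ns, 0, sqrt(spec$sigma_e_star2 / w))
    tibble(id = sires, y_star = unname(y), w = w, Rprime = Rp)
  })
}
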