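#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) are split between the sexes; in each later
#' generation every male of the previous generation is mated to randomly
#' chosen females from earlier generations and leaves
#' `cfg$progeny_per_sire` progeny of random sex. The result is acyclic, every
#' non-founder has both parents born in earlier generations, and the maternal
#' grandsire is recoverable through the dam.
#'
#' @param cfg A [sim_config()].
#' @return A sorted `ped_df` tibble with columns `id`, `sire`, `dam`, `sex`,
#'   `birth_year`, `generation`.
#' @export
#' @examples
#' ped <- simulate_pedigree(sim_config(seed = 1, n_founders = 10,
#'                                     n_generations = 2,
#'                                     progeny_per_sire = 2))
#' table(ped$generation)
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stream(cfg$seed, "pedigree", {
    n0 <- cfg$n_founders
    sex0 <- rep(c("M", "F"), length.out = n0)
    ped <- tibble(
      id = seq_len(n0),
      sire = NA_integer_,
      dam = NA_integer_,
      sex = sex0,
      birth_year = 1980L,
      generation = 0L
    )
    if (sum(sex0 == "M") == 0 || sum(sex0 == "F") == 0) {
      abort("pedigree needs founders of both sexes")
    }
    next_id <- n0 + 1L
    for (g in seq_len(cfg$n_generations)) {
      sires <- ped$id[ped$sex == "M" & ped$generation == g - 1L]
      dams_pool <- ped$id[ped$sex == "F" & ped$generation < g]
      if (!length(sires) || !length(dams_pool)) {
        abort(sprintf("no available %s for generation %d",
                      if (!length(sires)) "sires" else "dams", g))
      }
      n_prog <- length(sires) * cfg$progeny_per_sire
      prog <- tibble(
        id = seq.int(next_id, length.out = n_prog),
        sire = rep(sires, each = cfg$progeny_per_sire),
        dam = dams_pool[sample.int(length(dams_pool), n_prog, replace = TRUE)],
        sex = sample(c("M", "F"), n_prog, replace = TRUE),
        birth_year = 1980L + 4L * g,
        generation = g
      )
      next_id <- next_id + n_prog
      ped <- bind_rows(ped, prog)
    }
    as_pedigree(ped)
  })
}

#' Simulate true breeding values for the gait trait and longevity
#'
#' Draws per-animal true breeding values for the gait trait (animal scale)
#' and for longevity (sire-transmitting-ability scale, variance
#' `true_sire_variance`) jointly, with genetic correlation `true_rg`, and
#' transmits them down the pedigree: offspring receive the parent average
#' plus a Mendelian-sampling deviation with variance scaled by the parents'
#' inbreeding. As the population grows the sample covariance of the pairs
#' converges to \eqn{A \otimes G_{true}}.
#'
#' @param ped A pedigree.
#' @param cfg A [sim_config()].
#' @return Truth tibble with columns `id`, `bv_gait`, `bv_longevity`.
#' @export
simulate_breeding_values <- function(ped, cfg) {
  ped <- as_pedigree(ped)
  G2 <- true_genetic_covariance(cfg)
  with_stream(cfg$seed, "breeding-values", {
    pi <- ped_index(ped)
    n <- nrow(ped)
    s <- pi$sire
    d <- pi$dam
    f <- ped_inbreeding(ped)
    dvec <- mendelian_d(s, d, f)
    L <- chol2x2(G2)
    bv <- matrix(0, n, 2)
    z <- matrix(rnorm(2 * n), n, 2) %*% Matrix::t(L)
    for (i in seq_len(n)) {
      pa <- numeric(2)
      if (!is.na(s[i])) pa <- pa + 0.5 * bv[s[i], ]
      if (!is.na(d[i])) pa <- pa + 0.5 * bv[d[i], ]
      bv[i, ] <- pa + sqrt(dvec[i]) * z[i, ]
    }
    tibble(id = ped$id, bv_gait = bv[, 1], bv_longevity = bv[, 2])
  })
}

#' Simulate breeding values as sums of marker effects
#'
#' Marker-based counterpart of [simulate_breeding_values()]: every simulated
#' SNP receives a true bivariate effect (gait, longevity) drawn with
#' per-SNP covariance \eqn{G_{true} / (2\sum_k p_k(1-p_k))}, and an
#' animal's breeding values are the sums of its centred dosages times those
#' effects. Founders then have variance \eqn{G_{true}} in expectation and
#' transmission follows Mendelian segregation of the markers, so realized
#' genomic relationships describe the breeding values exactly — the
#' coherent truth model when the analysis uses a genomic or single-step
#' relationship matrix.
#'
#' @param gt A [genotype_matrix()] over all animals (from
#'   [simulate_genotypes()]).
#' @param cfg A [sim_config()].
#' @return Truth tibble `id`, `bv_gait`, `bv_longevity`, with the marker
#'   effect matrix in attribute `effects`.
#' @export
simulate_breeding_values_from_markers <- function(gt, cfg) {
  stopifnot(inherits(gt, "geno_matrix"))
  G2 <- true_genetic_covariance(cfg)
  with_stream(cfg$seed, "marker-effects", {
    geno <- gt$geno
    p <- colMeans(geno) / 2
    denom <- 2 * sum(p * (1 - p))
    L <- chol2x2(G2 / denom)
    alpha <- matrix(rnorm(2L * ncol(geno)), ncol = 2) %*% Matrix::t(L)
    bv <- sweep(geno, 2, 2 * p) %*% alpha
    out <- tibble(id = rownames(geno), bv_gait = bv[, 1],
                  bv_longevity = bv[, 2])
    attr(out, "effects") <- alpha
    out
  })
}

# 2x2 true genetic covariance: gait trait (animal scale) x longevity
# (sire-effect scale)
true_genetic_covariance <- function(cfg) {
  sg2 <- cfg$gait_h2 * cfg$gait_phenotypic_var
  ss2 <- cfg$true_sire_variance
  c12 <- cfg$true_rg * sqrt(sg2 * ss2)
  matrix(c(sg2, c12, c12, ss2), 2, 2)
}
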