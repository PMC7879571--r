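# Bivariate REML engine: MME oracles, constraint respect, recovery and the
# declared-non-convergence contract.

make_bitrait_data <- function(seed = 101, ns = 300, nfam = 80, npro = 4,
                              h2 = 0.3, rep_ = 0.6, rg = -0.4,
                              fixed = c("event_id", "gender", "age"),
                              covariates = c("velocity", "height")) {
  cfg <- sim_config(seed = seed, gait_h2 = h2, gait_repeatability = rep_,
                    true_rg = rg)
  ped <- halfsib_ped(ns, nfam, npro)
  tr <- simulate_breeding_values(ped, cfg)
  gait_ids <- ped$id[!is.na(ped$sire)]
  gr <- simulate_gait_records(ped, tr, cfg, horses = gait_ids)
  spec <- bitrait_spec(fixed = fixed, covariates = covariates,
                       sigma_u_star2 = cfg$true_sire_variance)
  pp <- simulate_pseudo_phenotypes(tr, cfg, sires = seq_len(ns), spec = spec)
  list(cfg = cfg, ped = ped, truth = tr, gait = gr, pseudo = pp, spec = spec,
       Ainv = build_A_inverse(ped))
}

test_that("MME solutions match a dense GLS oracle on a small joint model", {
  d <- make_bitrait_data(seed = 55, ns = 12, nfam = 6, npro = 2,
                         fixed = "gender", covariates = character(0))
  vc <- list(sigma_u2 = 0.12, sigma_pe2 = 0.1, sigma_e2 = 0.25, cov_u = -0.02)
  str <- gaitlong:::bitrait_structure(d$gait, d$pseudo, d$Ainv, d$spec)
  mme <- build_bitrait_mme(structure(str, class = "bitrait_structure_built"), vc)
  sol <- as.numeric(Matrix::solve(mme$C, mme$rhs))
  # dense oracle: GLS/BLUP on the stacked multivariate-normal formulation
  ids <- str$ids
  nH <- length(ids)
  A <- solve(as.matrix(d$Ainv))
  G2 <- matrix(c(vc$sigma_u2, vc$cov_u, vc$cov_u, d$spec$sigma_u_star2), 2)
  Gfull <- kronecker(G2, A)
  X <- as.matrix(str$X)
  Z1 <- as.matrix(str$Z1)
  Z2 <- as.matrix(str$Z2)
  n1 <- nrow(Z1)
  Zs <- rbind(cbind(Z1, matrix(0, n1, nH)),
              cbind(matrix(0, nrow(Z2), nH), Z2))
  Xs <- rbind(X, matrix(0, nrow(Z2), ncol(X)))
  R1 <- matrix(0, n1, n1)
  for (h in unique(str$horse)) {
    rows <- which(str$horse == h)
    R1[rows, rows] <- vc$sigma_pe2
  }
  diag(R1)[] <- diag(R1) + vc$sigma_e2
  R <- as.matrix(Matrix::bdiag(R1, diag(d$spec$sigma_e_star2 / d$pseudo$w)))
  V <- Zs %*% Gfull %*% t(Zs) + R
  Vi <- solve(V)
  y <- c(str$y1, str$y2)
  beta <- solve(t(Xs) %*% Vi %*% Xs, t(Xs) %*% Vi %*% y)
  u <- Gfull %*% t(Zs) %*% Vi %*% (y - Xs %*% beta)
  expect_equal(sol[mme$blocks$beta], as.numeric(beta), tolerance = 1e-6)
  expect_equal(sol[c(mme$blocks$u1, mme$blocks$u2)], as.numeric(u),
               tolerance = 1e-6)
})

test_that("scalar shrinkage and weight-scaling limits hold", {
  # single animal, one record, weight 1: MME reduces to 1-equation shrinkage
  spec <- bitrait_spec(sigma_u_star2 = 0.05, sigma_e_star2 = 0.4)
  Hinv <- Matrix::Diagonal(1)
  dimnames(Hinv) <- list("a", "a")
  pp <- tibble::tibble(id = "a", y_star = 0.3, w = 1)
  str <- gaitlong:::bitrait_structure(NULL, pp, Hinv, spec)
  vc <- list(sigma_u2 = 0.1, sigma_pe2 = 0, sigma_e2 = 0.2, cov_u = 0)
  mme <- build_bitrait_mme(structure(str, class = "bitrait_structure_built"), vc)
  sol <- as.numeric(Matrix::solve(mme$C, mme$rhs))
  shrink <- 0.3 * (0.05 / (0.05 + 0.4))   # u = y * su2/(su2 + se2/w)
  expect_equal(sol[mme$blocks$u2], shrink, tolerance = 1e-10)
  # equal weights behave as one unweighted model scaled by that weight
  pp2 <- tibble::tibble(id = "a", y_star = 0.3, w = 4)
  str2 <- gaitlong:::bitrait_structure(NULL, pp2, Hinv, spec)
  mme2 <- build_bitrait_mme(structure(str2, class = "bitrait_structure_built"), vc)
  sol2 <- as.numeric(Matrix::solve(mme2$C, mme2$rhs))
  expect_equal(sol2[mme2$blocks$u2], 0.3 * 0.05 / (0.05 + 0.1), tolerance = 1e-10)
})

test_that("REML recovers variance components and keeps fixed ones fixed", {
  d <- make_bitrait_data(seed = 77, ns = 400, nfam = 150, npro = 5,
                         h2 = 0.44, rep_ = 0.73, rg = -0.12)
  fit <- reml_bitrait(d$gait, d$pseudo, d$Ainv, d$spec)
  expect_true(fit$converged)
  vc <- fit$varcomp
  expect_equal(unname(vc$estimate[vc$component == "sigma_u_star2"]),
               d$spec$sigma_u_star2)
  expect_equal(unname(vc$estimate[vc$component == "sigma_e_star2"]),
               d$spec$sigma_e_star2)
  expect_true(all(vc$fixed[vc$component %in%
                             c("sigma_u_star2", "sigma_e_star2")]))
  der <- fit$derived
  h2 <- der[der$parameter == "h2", ]
  rep_ <- der[der$parameter == "repeatability", ]
  expect_lt(abs(h2$estimate - 0.44), 3 * h2$se)
  expect_lt(abs(rep_$estimate - 0.73), 3 * rep_$se)
  expect_gte(rep_$estimate, h2$estimate)
  # data-order invariance
  fit2 <- reml_bitrait(d$gait[sample.int(nrow(d$gait)), ],
                       d$pseudo[sample.int(nrow(d$pseudo)), ],
                       d$Ainv, d$spec)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-5)
  expect_equal(fit2$vc$sigma_u2, fit$vc$sigma_u2, tolerance = 1e-3)
})

test_that("a null genetic correlation is not declared significant", {
  d <- make_bitrait_data(seed = 99, ns = 350, nfam = 120, npro = 4,
                         h2 = 0.35, rep_ = 0.6, rg = 0)
  fit <- reml_bitrait(d$gait, d$pseudo, d$Ainv, d$spec)
  rg <- fit$derived[fit$derived$parameter == "r_g", ]
  expect_lt(abs(rg$estimate), 2.5 * rg$se)
})

test_that("derived parameters follow the variance-component algebra", {
  fake <- structure(list(
    vc = list(sigma_u2 = 0.44, sigma_pe2 = 0.29, sigma_e2 = 0.27,
              cov_u = sqrt(0.44 * 0.04)),
    vcov = NULL, spec = bitrait_spec(sigma_u_star2 = 0.04),
    repeated = TRUE, bivariate = TRUE), class = "bitrait_reml")
  d <- derived_parameters(fake)
  expect_equal(d$estimate[d$parameter == "h2"], 0.44)
  expect_equal(d$estimate[d$parameter == "repeatability"], 0.73)
  expect_equal(d$estimate[d$parameter == "r_g"], 1)   # boundary covariance
  fake$vc$sigma_pe2 <- 0
  fake$vc$sigma_e2 <- 0.56
  d2 <- derived_parameters(fake)
  expect_equal(d2$estimate[d2$parameter == "h2"],
               d2$estimate[d2$parameter == "repeatability"])
})

test_that("near-zero heritability is declared, never silently converged", {
  # the low-heritability walk-component behaviour: with h2 ~ 0.04 at the
  # study's family structure the genetic correlation is not identifiable
  # and the fit must say so
  d <- make_bitrait_data(seed = 121, ns = 350, nfam = 120, npro = 4,
                         h2 = 0.04, rep_ = 0.45, rg = -0.3)
  fit <- reml_bitrait(d$gait, d$pseudo, d$Ainv, d$spec)
  expect_type(fit$converged, "logical")
  if (!fit$converged) {
    expect_match(fit$message, "boundary|singular|converge")
  } else {
    # if the optimiser does settle, the reported uncertainty must expose the
    # non-identifiability
    rg <- fit$derived[fit$derived$parameter == "r_g", ]
    expect_true(is.na(rg$se) || rg$se > 0.25)
  }
})
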