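test_that("reliability follows R = 1 - t/sigma_u2 with clamping", {
  expect_equal(reliability(0.04, 0.04), 0)
  expect_equal(reliability(0, 0.04), 1)
  expect_equal(reliability(0.26 * 0.04, 0.04), 0.74)
  expect_warning(r <- reliability(0.05, 0.04), "clamped")
  expect_equal(r, 0)
  # MME oracle: one animal with w records of variance se2 each
  su2 <- 0.04; se2 <- 0.3; w <- 7
  pev <- 1 / (w / se2 + 1 / su2)
  R_mme <- (su2 - pev) / su2
  expect_equal(reliability(pev, su2), R_mme)
  expect_equal(weight_from_reliability(R_mme, se2 / su2), w)
})

test_that("weights reproduce the published extremes and monotonicity", {
  lambda <- (1 - 0.1195) / 0.1195   # survival-analysis heritability scale
  expect_equal(weight_from_reliability(0.404, lambda), 5.0, tolerance = 0.01)
  expect_equal(weight_from_reliability(0.974, lambda), 272, tolerance = 0.02)
  expect_equal(weight_from_reliability(0, lambda), 0)
  r <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(weight_from_reliability(r, lambda)) > 0))
  expect_error(weight_from_reliability(1, lambda), "infinite")
})

test_that("pruning removes exactly the parent-average information", {
  lambda <- 7
  ped <- data.frame(id = 1:3, sire = c(NA, NA, 1), dam = c(NA, NA, 2))
  # animal 3's reliability equals the parent-average alone: R' = 0
  Rpa_fun <- function(Rs, Rd) (Rs + Rd) / 4
  rec <- tibble::tibble(id = 1:3, R = c(0.6, 0.4, Rpa_fun(0.6, 0.4)))
  out <- suppressWarnings(prune_relative_info(rec, ped, lambda))
  expect_equal(out$Rprime[1:2], rec$R[1:2])   # founders keep their own info
  expect_equal(out$Rprime[3], 0, tolerance = 1e-8)
  # an unrelated animal is a fixed point
  lone <- tibble::tibble(id = 4, R = 0.55)
  ped2 <- rbind(ped, data.frame(id = 4, sire = NA, dam = NA))
  out2 <- prune_relative_info(lone, ped2, lambda)
  expect_equal(out2$Rprime, 0.55)
  # pruning never increases reliability
  rec3 <- tibble::tibble(id = 1:3, R = c(0.6, 0.4, 0.8))
  out3 <- prune_relative_info(rec3, ped, lambda)
  expect_true(all(out3$Rprime <= rec3$R + 1e-12))
})

test_that("pruning inverts the parent-average information combination", {
  # self-consistent oracle over a 3-generation chain: build each animal's
  # total reliability as the information-additive combination of its own
  # information and the parent average implied by the *pruned* parental
  # reliabilities, then check the fixed point recovers the own parts exactly
  lambda <- 7.37
  ped <- data.frame(id = 1:5, sire = c(NA, NA, 1, 1, 3),
                    dam = c(NA, NA, 2, 2, 4))
  T_own <- c(12, 5, 8, 0, 3)
  Tfun <- function(r) lambda * r / (1 - r)
  Rfun <- function(T) T / (T + lambda)
  Rp_true <- Rfun(T_own)
  R_tot <- numeric(5)
  for (i in 1:5) {
    s <- ped$sire[i]; d <- ped$dam[i]
    Rpa <- 0.25 * ((if (is.na(s)) 0 else Rp_true[s]) +
                     (if (is.na(d)) 0 else Rp_true[d]))
    R_tot[i] <- Rfun(T_own[i] + Tfun(Rpa))
  }
  out <- suppressWarnings(
    prune_relative_info(tibble::tibble(id = 1:5, R = R_tot), ped, lambda))
  expect_equal(out$Rprime, Rp_true, tolerance = 1e-8)
})

test_that("deregression round-trips exactly through the BLUP equations", {
  cfg <- small_cfg(seed = 19)
  ped <- simulate_pedigree(cfg)
  ids <- as.character(sample(ped$id, 30))
  A <- sire_mgs_matrix(ped, ids)
  set.seed(11)
  su2 <- 0.04; se2 <- 0.29
  rec <- tibble::tibble(id = ids, ebv = rnorm(30, 0, 0.15),
                        w = runif(30, 0.5, 40))
  dr <- deregress(rec, solve(A), su2, se2)
  Dinv <- diag(dr$w / se2)
  lhs <- Dinv + solve(A) / su2
  back <- solve(lhs, Dinv %*% dr$y_star)
  expect_equal(as.numeric(back), rec$ebv, tolerance = 1e-10)
  # weights -> infinity with A = I: y* = uhat
  rec_inf <- tibble::tibble(id = c("p", "q"), ebv = c(0.1, -0.2), w = 1e12)
  I2 <- diag(2); dimnames(I2) <- list(c("p", "q"), c("p", "q"))
  dr_inf <- deregress(rec_inf, I2, su2, se2)
  expect_equal(dr_inf$y_star, rec_inf$ebv, tolerance = 1e-9)
  # single unrelated animal: classical y* = uhat / R'
  lam <- se2 / su2
  w1 <- weight_from_reliability(0.5, lam)
  one <- deregress(tibble::tibble(id = "s", ebv = 0.08, w = w1),
                   matrix(1, 1, 1, dimnames = list("s", "s")), su2, se2)
  expect_equal(one$y_star, 0.08 / 0.5)
})

test_that("retention filters on cleaned reliability and reports a summary", {
  rec <- tibble::tibble(id = 1:10, Rprime = seq(0.05, 0.95, by = 0.1),
                        y_star = rnorm(10))
  expect_equal(nrow(retain(rec, 0)), 10)
  expect_equal(nrow(retain(rec, 1)), 0)
  kept <- retain(rec, 0.40)
  expect_equal(nrow(kept), sum(rec$Rprime >= 0.40))
  expect_true(all(c("variable", "n", "mean", "min", "max") %in%
                    names(attr(kept, "summary"))))
})

test_that("the full deregression pipeline rebuilds consistent reliabilities", {
  # approximate round trip: reliabilities implied by the rebuilt MME from
  # (y*, w, A) match the pruned-and-weighted inputs within 0.02
  cfg <- sim_config(seed = 37, n_founders = 120, n_generations = 1,
                    progeny_per_sire = 25)
  ped <- simulate_pedigree(cfg)
  tr <- simulate_breeding_values(ped, cfg)
  ca <- simulate_careers(ped, tr, cfg)
  fit <- fit_survival(ca)
  dr <- suppressWarnings(deregress_ebv(fit, ped, threshold = 0.2))
  expect_true(all(dr$Rprime >= 0.2))
  expect_true(all(dr$w > 0))
  # approximate reliability round-trip: the MME rebuilt from (w, A) should
  # reproduce the *original* (unpruned) reliabilities, since the pedigree
  # links restore the relative-derived information the pruning removed
  lambda <- (1 - fit$h2) / fit$h2
  su2 <- fit$sigma_s2; se2 <- lambda * su2
  A <- sire_mgs_matrix(ped, as.character(dr$id))
  Cinv <- solve(diag(dr$w / se2) + solve(A) / su2)
  R_back <- 1 - diag(Cinv) / su2
  expect_lt(mean(abs(R_back - dr$R)), 0.02)
})
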