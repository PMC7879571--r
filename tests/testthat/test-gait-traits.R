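test_that("horse-effect BLUPs shrink but track the simulated truth", {
  meas <- simulate_gait_measurements(n_horses = 400, gait = "trot", seed = 3)
  eff <- suppressMessages(estimate_horse_effects(meas))
  expect_setequal(unique(eff$variable), gaitlong:::gait_variables("trot"))
  # closed-form shrinkage oracle for one variable: with n records per horse,
  # BLUP accuracy^2 = n*vr/(n*vr+1) with vr the horse/residual variance ratio
  one <- meas[meas$variable == "dorsoventral_activity", ]
  fit <- suppressMessages(lme4::lmer(
    value ~ gender + factor(age) + factor(event_id) + recording_type +
      velocity + (1 | horse), data = one))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vr <- vc$vcov[1] / vc$vcov[2]
  acc2 <- 2 * vr / (2 * vr + 1)
  e <- eff[eff$variable == "dorsoventral_activity", ]
  # empirical squared correlation with the realised horse means ~ acc2 bound
  horse_means <- tapply(one$value, one$horse, mean)
  r <- cor(e$effect, horse_means[as.character(e$horse)])
  expect_gt(r, sqrt(acc2) - 0.15)
  # all-identical records give zero effects
  flat <- meas
  flat$value <- 1
  eff0 <- suppressWarnings(suppressMessages(estimate_horse_effects(flat)))
  expect_lt(max(abs(eff0$effect)), 1e-8)
})

test_that("per-gait PCA has orthonormal, sign-fixed loadings", {
  meas <- simulate_gait_measurements(n_horses = 300, gait = "canter", seed = 5)
  eff <- suppressMessages(estimate_horse_effects(meas))
  pca <- pca_per_gait(eff, n_components = 3)
  L <- pca$loadings
  expect_equal(nrow(L), 7)    # canter has no symmetry variable
  expect_equal(crossprod(L), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  for (c in 1:3) expect_gt(L[which.max(abs(L[, c])), c], 0)
  # eigenvalues conserve total standardised variance
  expect_equal(sum(pca$eigenvalues), 7, tolerance = 1e-8)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  # block structure puts the top-3 share in a plausible envelope
  expect_gt(sum(pca$var_explained), 0.5)
})

test_that("analytic eigenvectors emerge for a correlated pair", {
  # two perfectly correlated variables among independent others: PC1 loads
  # equally on the pair (hand-computed 2x2 eigendecomposition)
  set.seed(8)
  n <- 500
  x <- rnorm(n)
  X <- cbind(a = x, b = x, c = rnorm(n), d = rnorm(n))
  pca <- pca_per_gait(X, n_components = 2)
  L1 <- pca$loadings[, 1]
  expect_equal(unname(abs(L1["a"])), unname(abs(L1["b"])), tolerance = 1e-6)
  expect_equal(unname(abs(L1["a"])), sqrt(0.5), tolerance = 0.05)
  # mutually uncorrelated variables: each PC explains ~ 1/4
  Xi <- matrix(rnorm(4 * 2000), ncol = 4)
  pci <- pca_per_gait(Xi, n_components = 4)
  expect_lt(max(abs(pci$var_explained - 0.25)), 0.05)
})

test_that("recording-level scores centre, duplicate and add within-horse noise", {
  meas <- simulate_gait_measurements(n_horses = 250, gait = "trot", seed = 9)
  eff <- suppressMessages(estimate_horse_effects(meas))
  pca <- pca_per_gait(eff)
  sc <- pc_scores_per_recording(meas, pca)
  expect_equal(nrow(sc), 500)   # two recordings per horse
  # a recording exactly at the per-variable means scores zero on every PC
  vars <- rownames(pca$loadings)
  mean_rec <- tidyr::crossing(horse = 0L, recording_type = "working",
                              variable = vars)
  wide <- tidyr::pivot_wider(meas[meas$variable %in% vars,
                                  c("horse", "recording_type", "variable", "value")],
                             names_from = "variable", values_from = "value")
  mean_rec$value <- colMeans(as.matrix(wide[vars]))[mean_rec$variable]
  sc0 <- pc_scores_per_recording(rbind(
    meas[c("horse", "recording_type", "variable", "value")],
    mean_rec[c("horse", "recording_type", "variable", "value")]), pca)
  expect_lt(max(abs(sc0[sc0$horse == 0, c("PC1", "PC2", "PC3")])), 1e-8)
  # duplicated recording gives identical scores
  dup <- rbind(meas, dplyr::mutate(meas[meas$horse == 1, ], horse = 9999L))
  scd <- pc_scores_per_recording(dup, pca)
  expect_equal(as.matrix(scd[scd$horse == 9999, -(1:2)]),
               as.matrix(scd[scd$horse == 1, -(1:2)]), ignore_attr = TRUE)
  # recordings add within-horse noise: score variance over recordings is at
  # least the variance of the per-horse averages
  sbar <- stats::aggregate(PC1 ~ horse, data = sc, FUN = mean)
  expect_gte(var(sc$PC1), var(sbar$PC1) - 1e-8)
  # a recording missing one variable is withheld with a warning
  expect_warning(
    pc_scores_per_recording(meas[-1, ], pca), "withheld")
})
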