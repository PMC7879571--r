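# GWAS back-solution: reconstruction identities, null calibration, planted
# signals.

make_gwas_data <- function(seed = 61, n = 300, m = 800, qtl = NULL,
                           qtl_var = 0) {
  set.seed(seed)
  geno <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(seq_len(m), each = n)]),
                 n, m, dimnames = list(paste0("a", seq_len(n)), NULL))
  map <- tibble::tibble(snp_id = sprintf("s%04d", seq_len(m)),
                        chr = as.character(rep(1:10, length.out = m)),
                        pos = seq_len(m) * 100L)
  gt <- genotype_matrix(geno, map)
  G <- build_G(gt)
  Gw <- 0.95 * G + 0.05 * diag(n)
  dimnames(Gw) <- dimnames(G)
  sigma_u2 <- 0.05
  sigma_e2 <- 0.3
  L <- chol(Gw * sigma_u2)
  u <- as.numeric(crossprod(L, rnorm(n)))
  if (!is.null(qtl)) {
    cd <- gaitlong:::centred_dosages(gt)
    beta <- sqrt(qtl_var / (2 * mean(cd$Z[, qtl]^2) / 2))
    beta <- sqrt(qtl_var) / sd(cd$Z[, qtl])
    u <- u + cd$Z[, qtl] * beta
  }
  w <- runif(n, 5, 50)
  y <- u + rnorm(n, 0, sqrt(sigma_e2 / w))
  pseudo <- tibble::tibble(id = rownames(geno), y_star = y, w = w)
  list(gt = gt, G = G, Gw = Gw, pseudo = pseudo, sigma_u2 = sigma_u2,
       sigma_e2 = sigma_e2, u = u)
}

test_that("back-solved effects reconstruct the genomic breeding values", {
  d <- make_gwas_data(seed = 71)
  # the reconstruction identity holds for the exact VanRaden G and breeding
  # values in its row space (any genomic BLUP solution lies there)
  set.seed(72)
  u_range <- as.numeric(d$G %*% rnorm(nrow(d$G))) / 2
  names(u_range) <- rownames(d$G)
  a <- backsolve_snp_effects(u_range, d$gt, d$G)
  cd <- gaitlong:::centred_dosages(d$gt)
  expect_equal(as.numeric(cd$Z %*% a), unname(u_range), tolerance = 1e-6)
  # zero breeding values give zero effects
  a0 <- backsolve_snp_effects(setNames(rep(0, nrow(d$gt$geno)),
                                       rownames(d$gt$geno)), d$gt, d$Gw)
  expect_equal(max(abs(a0)), 0)
})

test_that("a single marker reduces to the GLS regression coefficient", {
  set.seed(31)
  n <- 80
  g <- rbinom(n, 2, 0.4)
  geno <- matrix(g, n, 1, dimnames = list(paste0("a", 1:n), NULL))
  z <- g - mean(g)
  y <- 0.3 * z + rnorm(n, 0, 0.5)
  # G for one SNP: z z' / (2pq); effect back-solved from u = GLS projection
  p <- mean(g) / 2
  scale <- 2 * p * (1 - p)
  G1 <- tcrossprod(z) / scale + diag(n) * 1e-6
  dimnames(G1) <- list(rownames(geno), rownames(geno))
  uhat <- as.numeric(G1 %*% solve(G1 + diag(n) * 0.25, y))  # ridge BLUP
  a <- backsolve_snp_effects(setNames(uhat, rownames(geno)), geno, G1)
  # oracle: the same shrunken regression written marker-wise
  a_oracle <- sum(z * uhat) / (scale * sum(z^2) / scale)
  expect_equal(unname(a[1]), a_oracle * 1, tolerance = 1e-6)
  # and it is proportional to the OLS coefficient of uhat on z
  expect_equal(unname(a[1]), unname(coef(lm(uhat ~ z))[2]), tolerance = 1e-6)
})

test_that("p-values are uniform under the polygenic null", {
  d <- make_gwas_data(seed = 81, n = 400, m = 1000)
  fit <- fit_gblup(d$pseudo, d$Gw, d$sigma_u2, d$sigma_e2)
  tab <- snp_pvalues(fit$uhat, fit$C, d$gt, d$Gw, d$sigma_u2)
  expect_true(all(tab$neg_log10_p[!tab$flagged] >= 0))
  ks <- suppressWarnings(ks.test(tab$p[!tab$flagged], "punif"))
  # KS distance below the alpha = 0.01 critical value
  expect_gt(ks$p.value, 0.01)
  # scale invariance: multiplying pseudo-phenotypes by c scales effects by c
  # and leaves p-values unchanged
  d2 <- d
  d2$pseudo$y_star <- 3 * d$pseudo$y_star
  fit2 <- fit_gblup(d2$pseudo, d$Gw, d$sigma_u2 * 9, d$sigma_e2 * 9)
  tab2 <- snp_pvalues(fit2$uhat, fit2$C, d$gt, d$Gw, d$sigma_u2 * 9)
  expect_equal(tab2$effect, 3 * tab$effect, tolerance = 1e-6)
  expect_equal(tab2$p, tab$p, tolerance = 1e-6)
})

test_that("a planted QTL rises to the top of the association table", {
  hits <- sapply(1:5, function(r) {
    d <- make_gwas_data(seed = 200 + r, n = 300, m = 600, qtl = 123,
                        qtl_var = 0.05)
    fit <- fit_gblup(d$pseudo, d$Gw, d$sigma_u2 + 0.05, d$sigma_e2)
    a <- backsolve_snp_effects(fit$uhat, d$gt, d$Gw)
    which.max(abs(a))
  })
  expect_gte(mean(hits == 123), 0.8)
})

test_that("the significance report thresholds and annotates correctly", {
  d <- make_gwas_data(seed = 91, n = 200, m = 300)
  fit <- fit_gblup(d$pseudo, d$Gw, d$sigma_u2, d$sigma_e2)
  tab <- snp_pvalues(fit$uhat, fit$C, d$gt, d$Gw, d$sigma_u2)
  expect_equal(nrow(significance_report(tab, threshold = 0)),
               sum(!is.na(tab$neg_log10_p)))
  expect_equal(nrow(significance_report(tab[0, ], 5)), 0)
  # expected tail count under the null ~ m * 2 * Phi(-sqrt(5 * 2 * ln 10))
  m <- sum(!tab$flagged)
  expected <- m * 2 * pnorm(-sqrt(5 * 2 * log(10)))
  observed <- nrow(significance_report(tab, 5))
  expect_lte(observed, max(5, 10 * expected))
  expect_true("maf" %in% names(tab))
  # all-zero phenotypes: every p-value is 1 under the two-sided convention
  d0 <- d
  d0$pseudo$y_star <- 0
  fit0 <- fit_gblup(d0$pseudo, d$Gw, d$sigma_u2, d$sigma_e2)
  tab0 <- snp_pvalues(fit0$uhat, fit0$C, d$gt, d$Gw, d$sigma_u2)
  expect_true(all(tab0$p[!tab0$flagged] == 1))
})

test_that("manhattan plot builds from an association table", {
  d <- make_gwas_data(seed = 95, n = 100, m = 200)
  fit <- fit_gblup(d$pseudo, d$Gw, d$sigma_u2, d$sigma_e2)
  tab <- snp_pvalues(fit$uhat, fit$C, d$gt, d$Gw, d$sigma_u2)
  p <- plot_manhattan(tab)
  expect_s3_class(p, "ggplot")
})
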