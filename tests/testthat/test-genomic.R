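test_that("QC cascade applies the filters in canonical order with full bookkeeping", {
  set.seed(3)
  n <- 80; m <- 14
  geno <- matrix(rbinom(n * m, 2, 0.35), n, m,
                 dimnames = list(paste0("a", seq_len(n)), NULL))
  geno[, 3] <- 0L                                   # monomorphic -> MAF
  geno[, 4] <- c(rep(0L, 40), rep(2L, 40))          # extreme HWE failure
  geno[seq_len(20), 5] <- NA                        # call rate 0.75
  geno[1:40, 6] <- rbinom(40, 2, 0.2)               # chips disagree on MAF
  geno[41:80, 6] <- rbinom(40, 2, 0.6)
  map <- tibble::tibble(
    snp_id = paste0("s", seq_len(m)),
    chr = c("0", "X", rep("5", 5), "5", rep("6", m - 8)),
    pos = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 3L, 9L:(9L + m - 9L)))
  gt <- genotype_matrix(geno, map, chip = rep(c("A", "B"), each = 40))
  res <- qc_cascade(gt)
  rep_ <- res$report
  expect_equal(rep_$filter,
               c("unplaced", "sex_chromosomes", "duplicates", "maf", "hwe",
                 "call_rate", "chip_maf_consistency"))
  expect_equal(rep_$n_removed[1:3], c(1L, 1L, 1L))
  expect_gte(rep_$n_removed[rep_$filter == "maf"], 1L)
  expect_gte(rep_$n_removed[rep_$filter == "hwe"], 1L)
  expect_equal(rep_$n_removed[rep_$filter == "call_rate"], 1L)
  expect_gte(rep_$n_removed[rep_$filter == "chip_maf_consistency"], 1L)
  # conservation: initial - sum(removed) = final, monotone
  expect_equal(m - sum(rep_$n_removed), dplyr::last(rep_$n_remaining))
  expect_true(all(diff(rep_$n_remaining) <= 0))
  expect_equal(ncol(res$gt$geno), dplyr::last(rep_$n_remaining))
})

test_that("an exact-HWE oracle agrees with the chi-square filter", {
  # genotype counts (AA=30, Aa=0, aa=30): chi-square p far below 1e-6
  geno <- matrix(c(rep(0L, 30), rep(2L, 30)), ncol = 1,
                 dimnames = list(paste0("a", 1:60), NULL))
  p <- gaitlong:::hwe_pvalue(geno)
  stat <- stats::chisq.test(c(30, 0, 30),
                            p = c(0.25, 0.5, 0.25))$statistic  # p = 0.5 here
  expect_lt(p, 1e-6)
  expect_equal(p, pchisq(60, df = 1, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("replaying the published removal counts conserves the totals", {
  rep_ <- qc_replay(606343,
                    c(maf = 196864, hwe = 25596, call_rate = 6614,
                      chip_maf = 1582))
  expect_equal(dplyr::last(rep_$n_remaining), 375687L)
  expect_error(qc_replay(100, c(a = 60, b = 60)), "negative|conserve")
})

test_that("VanRaden G behaves on edge cases and duplicates", {
  geno <- matrix(c(0L, 1L, 2L, 0L, 2L, 1L), 2, 3, byrow = TRUE,
                 dimnames = list(c("x", "y"), NULL))
  map <- tibble::tibble(snp_id = paste0("s", 1:3), chr = "1", pos = 1:3)
  G <- build_G(genotype_matrix(geno, map))
  expect_gt(G["x", "x"], 0)
  # identical twins: off-diagonal equals both diagonals
  geno2 <- rbind(geno, z = geno["x", ])
  G2 <- build_G(geno2)
  expect_equal(G2["x", "z"], G2["x", "x"])
  expect_equal(G2["z", "z"], G2["x", "x"])
  # single animal: 1x1 with positive diagonal
  G1 <- build_G(matrix(c(0L, 1L, 2L), 1, dimnames = list("solo", NULL)),
                freq = c(0.3, 0.5, 0.4))
  expect_equal(dim(G1), c(1L, 1L))
  expect_gt(G1[1, 1], 0)
  expect_error(build_G(matrix(2L, 3, 4, dimnames = list(letters[1:3], NULL))),
               "monomorphic")
})

test_that("H-inverse matches the dense partitioned oracle", {
  cfg <- sim_config(seed = 13, n_founders = 40, n_generations = 2,
                    progeny_per_sire = 4, n_snps = 500)
  ped <- simulate_pedigree(cfg)
  gt <- simulate_genotypes(ped, cfg)
  A <- build_A(ped)
  Ai <- build_A_inverse(ped)
  gen_ids <- as.character(sample(ped$id[ped$generation == 2], 50))
  G <- build_G(genotype_matrix(gt$geno[gen_ids, ], gt$map))
  Hi <- build_H_inverse(Ai, G, gen_ids, ped, blend = 0.05, tune = TRUE)
  # dense oracle via the textbook partitioned H
  A22 <- A[gen_ids, gen_ids]
  nd <- nrow(A22)
  offd <- function(X) (sum(X) - sum(diag(X))) / (nd * (nd - 1))
  b <- (mean(diag(A22)) - offd(A22)) / (mean(diag(G)) - offd(G))
  a <- mean(diag(A22)) - b * mean(diag(G))
  Gw <- 0.95 * (a + b * G) + 0.05 * A22
  k <- match(gen_ids, rownames(A))
  A12 <- A[-k, k]; A22i <- solve(A22)
  H <- A
  H[-k, -k] <- A[-k, -k] + A12 %*% A22i %*% (Gw - A22) %*% A22i %*% t(A12)
  H[-k, k] <- A12 %*% A22i %*% Gw
  H[k, -k] <- t(H[-k, k])
  H[k, k] <- Gw
  expect_lt(max(abs(solve(H) -
                      as.matrix(Hi)[rownames(H), rownames(H)])), 1e-6)
  # no genotyped animals: H-inverse is exactly A-inverse
  H0 <- build_H_inverse(Ai, G, character(0), ped)
  expect_equal(as.matrix(H0), as.matrix(Ai), tolerance = 0)
  # all pedigree info, G = A22, no tuning/blending: H-inverse = A-inverse
  Hsame <- build_H_inverse(Ai, A22, gen_ids, ped, blend = 0, tune = FALSE)
  expect_lt(max(abs(as.matrix(Hsame) - as.matrix(Ai))), 1e-6)
})

test_that("coordinate-format export writes the lower triangle", {
  M <- matrix(c(2, 1, 1, 3), 2, dimnames = list(c("a", "b"), c("a", "b")))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_coordinate_matrix(M, path)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(df), 3)
  expect_equal(df$value[df$i == 2 & df$j == 1], 1)
})
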