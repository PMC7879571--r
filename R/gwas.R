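# GWAS of longevity by back-solving SNP effects from a (single-step) GBLUP
# fit of the weighted pseudo-phenotypes, with p-values from the
# prediction-error covariance of the genomic breeding values.

#' Weighted GBLUP of longevity pseudo-phenotypes
#'
#' Solves the mixed-model equations for `y* = u + e` with
#' `Var(u) = sigma_u2 * K` and `Var(e) = diag(sigma_e2 / w)`, returning the
#' breeding-value solutions and the full prediction-error covariance
#' (direct inversion of the coefficient matrix: exactness over
#' scalability, intended for desk-scale panels).
#'
#' @param pseudo Tibble `id`, `y_star`, `w`.
#' @param K Relationship matrix over all animals (dimnames = ids): a
#'   blended genomic matrix or a dense H.
#' @param sigma_u2,sigma_e2 Variance components on the pseudo-phenotype
#'   scale.
#' @return List `uhat` (named vector), `C` (prediction-error covariance of
#'   `uhat`), `sigma_u2`, `ids`.
#' @export
fit_gblup <- function(pseudo, K, sigma_u2, sigma_e2) {
  check_columns(pseudo, c("id", "y_star", "w"), "pseudo-phenotypes")
  ids <- rownames(K)
  if (!all(as.character(pseudo$id) %in% ids)) {
    abort("pseudo-phenotyped animals must be indexed in K")
  }
  Kinv <- tryCatch(solve(as.matrix(K)), error = function(e) {
    abort("relationship matrix is singular; blend it toward the pedigree block")
  })
  n <- length(ids)
  d <- numeric(n)
  r <- numeric(n)
  at <- match(as.character(pseudo$id), ids)
  d[at] <- pseudo$w / sigma_e2
  r[at] <- pseudo$y_star * pseudo$w / sigma_e2
  Cmat <- Kinv / sigma_u2
  diag(Cmat) <- diag(Cmat) + d
  Cinv <- solve(Cmat)
  uhat <- as.numeric(Cinv %*% r)
  list(uhat = setNames(uhat, ids), C = Cinv, sigma_u2 = sigma_u2, ids = ids)
}

#' Back-solve SNP effects from genomic breeding values
#'
#' \deqn{\hat a = M' G^{-1} \hat u_g / (2\sum_k p_k(1-p_k))}
#' with `M` the centred dosage matrix that built `G`; reconstructing
#' \eqn{M \hat a} returns the genomic part of \eqn{\hat u_g}.
#'
#' @param u_g Breeding values of the genotyped animals (named vector).
#' @param gt Genotypes ([genotype_matrix()] or dosage matrix) of those
#'   animals, identical to what built `G`.
#' @param G Genomic relationship matrix from [build_G()], or its blended
#'   form. The exact VanRaden G is singular by construction (centring makes
#'   the all-ones vector a null direction), so the solve is regularised by a
#'   relative ridge of `ridge` times the mean diagonal; breeding values lie
#'   in the row space, leaving the back-solution unaffected.
#' @param ridge Relative regularisation of the G solve.
#' @return Named vector of SNP effects.
#' @export
backsolve_snp_effects <- function(u_g, gt, G, ridge = 1e-10) {
  cd <- centred_dosages(gt)
  ids <- rownames(cd$Z)
  if (!is.null(names(u_g))) u_g <- u_g[ids]
  if (length(u_g) != nrow(cd$Z)) abort("`u_g` must cover the genotyped animals")
  Gg <- as.matrix(G[ids, ids])
  diag(Gg) <- diag(Gg) + ridge * mean(diag(Gg))
  Ginv_u <- tryCatch(solve(Gg, u_g), error = function(e) {
    abort("G is singular; use a blended genomic matrix")
  })
  setNames(as.numeric(crossprod(cd$Z, Ginv_u)) / cd$scale, colnames(cd$Z))
}

#' SNP-effect table with p-values
#'
#' Sampling variances follow the prediction-error route:
#' \deqn{Var(\hat a_k) = m_k' G^{-1} (\sigma_u^2 G - C) G^{-1} m_k /
#'  (2\sum p(1-p))^2}
#' with `C` the prediction-error covariance of the genomic breeding values;
#' p-values are two-sided normal on \eqn{\hat a / \sqrt{Var}}. SNPs whose
#' variance is numerically non-positive are flagged and their p-value
#' withheld.
#'
#' @param u_g Genotyped-animal breeding values (named).
#' @param C_g Prediction-error covariance of `u_g` (genotyped block).
#' @param gt Genotypes of those animals.
#' @param G Genomic relationship matrix.
#' @param sigma_u2 Genetic variance on the pseudo-phenotype scale.
#' @return Tibble `snp_id`, `chr`, `pos`, `maf`, `effect`, `se`, `p`,
#'   `neg_log10_p`, `flagged`.
#' @export
snp_pvalues <- function(u_g, C_g, gt, G, sigma_u2) {
  cd <- centred_dosages(gt)
  ids <- rownames(cd$Z)
  effect <- backsolve_snp_effects(u_g, gt, G)
  Gg <- as.matrix(G[ids, ids])
  diag(Gg) <- diag(Gg) + 1e-10 * mean(diag(Gg))
  Ginv <- solve(Gg)
  Q <- Ginv %*% (sigma_u2 * Gg - as.matrix(C_g[ids, ids])) %*% Ginv
  QZ <- Q %*% cd$Z
  v <- colSums(cd$Z * QZ) / cd$scale^2
  flagged <- v <= 0
  se <- sqrt(pmax(v, 0))
  z <- ifelse(flagged, NA_real_, effect / ifelse(se > 0, se, Inf))
  p <- 2 * pnorm(-abs(z))
  p[!flagged & se == 0] <- 1
  map <- if (inherits(gt, "geno_matrix")) gt$map else
    tibble(snp_id = colnames(cd$Z), chr = NA_character_, pos = NA_integer_)
  tibble(
    snp_id = names(effect), chr = map$chr[match(names(effect), map$snp_id)],
    pos = map$pos[match(names(effect), map$snp_id)],
    maf = pmin(cd$freq, 1 - cd$freq),
    effect = unname(effect), se = unname(se), p = unname(p),
    neg_log10_p = unname(-log10(p)),
    flagged = unname(flagged)
  )
}

#' Significant-SNP report
#'
#' Rows above a \eqn{-\log_{10} p} threshold, annotated with MAF (hits near
#' the QC threshold deserve scrutiny) and ordered by significance.
#'
#' @param table Output of [snp_pvalues()].
#' @param threshold Minimum \eqn{-\log_{10} p} (study plots used 5).
#' @return The qualifying subset.
#' @export
significance_report <- function(table, threshold = 5) {
  check_columns(table, c("snp_id", "neg_log10_p"), "SNP table")
  table %>%
    filter(!is.na(.data$neg_log10_p), .data$neg_log10_p >= threshold) %>%
    arrange(dplyr::desc(.data$neg_log10_p))
}
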