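# Genomic relationship matrix and the single-step H-inverse.

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \eqn{G = M M' / (2\sum_k p_k(1-p_k))} with \eqn{M} the dosage matrix
#' centred at twice the observed allele frequencies. Residual missingness is
#' mean-imputed before centring.
#'
#' @param gt A [genotype_matrix()] or a plain dosage matrix with animal ids
#'   as rownames.
#' @param freq Optional per-SNP allele frequencies for the centring; defaults
#'   to the observed frequencies (degenerate panels, e.g. a single animal,
#'   need external frequencies).
#' @return Dense symmetric matrix over the genotyped animals with attributes
#'   `scale` (the denominator) and `freq` (the frequencies used).
#' @export
build_G <- function(gt, freq = NULL) {
  geno <- if (inherits(gt, "geno_matrix")) gt$geno else as.matrix(gt)
  p <- freq %||% (colMeans(geno, na.rm = TRUE) / 2)
  poly <- p > 0 & p < 1
  if (!any(poly)) abort("all SNPs are monomorphic; G is undefined")
  denom <- 2 * sum(p * (1 - p))
  M <- geno
  if (anyNA(M)) {
    for (k in which(colSums(is.na(M)) > 0)) {
      M[is.na(M[, k]), k] <- 2 * p[k]
    }
  }
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  G <- as.matrix(G)
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "scale") <- denom
  attr(G, "freq") <- p
  attr(G, "is_inverse") <- FALSE
  G
}

# centred dosage matrix and VanRaden scale, shared by build_G and the GWAS
# back-solution (which must use the identical centring)
centred_dosages <- function(gt) {
  geno <- if (inherits(gt, "geno_matrix")) gt$geno else as.matrix(gt)
  p <- colMeans(geno, na.rm = TRUE) / 2
  M <- geno
  if (anyNA(M)) {
    for (k in which(colSums(is.na(M)) > 0)) M[is.na(M[, k]), k] <- 2 * p[k]
  }
  list(Z = sweep(M, 2, 2 * p), scale = 2 * sum(p * (1 - p)), freq = p)
}

#' Single-step combined relationship inverse H^-1
#'
#' \deqn{H^{-1} = A^{-1} + \begin{pmatrix}0&0\\0&G_w^{-1}-A_{22}^{-1}\end{pmatrix}}
#' on the genotyped block, where \eqn{G_w = (1-b)\,G^\ast + b\,A_{22}} blends
#' the (optionally tuned) genomic matrix with the pedigree block to guarantee
#' invertibility, and tuning rescales \eqn{G} so its mean diagonal and mean
#' off-diagonal match those of \eqn{A_{22}}.
#'
#' @param Ainv Sparse pedigree relationship inverse from
#'   [build_A_inverse()] (dimnames = all animals).
#' @param G Genomic matrix from [build_G()] over the genotyped animals.
#' @param genotyped Ids of the genotyped animals (must index rows of `G`).
#' @param ped The full pedigree (used for the \eqn{A_{22}} block).
#' @param blend Weight on \eqn{A_{22}} in the blend (default 0.05).
#' @param tune Match G's means to the pedigree block (default `TRUE`).
#' @return Sparse symmetric matrix over all animals, attribute
#'   `genotyped` carrying the genotyped ids; equals `Ainv` exactly when
#'   `genotyped` is empty.
#' @export
build_H_inverse <- function(Ainv, G, genotyped, ped, blend = 0.05,
                            tune = TRUE) {
  ids <- rownames(Ainv)
  genotyped <- as.character(genotyped)
  if (!length(genotyped)) {
    attr(Ainv, "genotyped") <- character(0)
    return(Ainv)
  }
  if (!all(genotyped %in% ids)) {
    abort(paste("genotyped animals absent from pedigree:",
                paste(setdiff(genotyped, ids), collapse = ", ")))
  }
  if (!all(genotyped %in% rownames(G))) {
    abort("`G` must cover every genotyped animal")
  }
  Gg <- G[genotyped, genotyped, drop = FALSE]
  A22 <- sire_mgs_matrix(ped, genotyped)
  if (tune) {
    nd <- nrow(Gg)
    offd <- function(X) (sum(X) - sum(Matrix::diag(X))) / (nd * (nd - 1))
    # solve mean(diag) and mean(offdiag) moment equations for G* = a + b G
    b <- (mean(Matrix::diag(A22)) - offd(A22)) /
      max(mean(Matrix::diag(Gg)) - offd(Gg), .Machine$double.eps)
    a <- mean(Matrix::diag(A22)) - b * mean(Matrix::diag(Gg))
    Gg <- a + b * Gg
  }
  Gw <- (1 - blend) * Gg + blend * A22
  ch <- tryCatch(chol(Gw), error = function(e) NULL)
  if (is.null(ch)) {
    abort("blended genomic matrix is singular; increase `blend`")
  }
  Gw_inv <- chol2inv(ch)
  A22_inv <- solve(A22)
  k <- match(genotyped, ids)
  n <- length(ids)
  delta <- Gw_inv - A22_inv
  Hinv <- as(Ainv, "CsparseMatrix") +
    sparseMatrix(i = rep(k, times = length(k)),
                 j = rep(k, each = length(k)),
                 x = as.numeric(delta), dims = c(n, n),
                 dimnames = list(ids, ids))
  Hinv <- forceSymmetric((Hinv + Matrix::t(Hinv)) / 2)
  attr(Hinv, "is_inverse") <- TRUE
  attr(Hinv, "genotyped") <- genotyped
  Hinv
}

#' Export a symmetric (relationship) matrix as coordinate-format text
#'
#' Writes lower-triangle `i j value` triplets (1-based indices in the
#' matrix's own id order) for interoperability with mixed-model tools.
#'
#' @param X Matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coordinate_matrix <- function(X, path) {
  X <- as(as(Matrix(X, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  keep <- X@i >= X@j
  df <- tibble(i = X@i[keep] + 1L, j = X@j[keep] + 1L, value = X@x[keep]) %>%
    arrange(.data$i, .data$j)
  readr::write_tsv(df, path)
  invisible(path)
}
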