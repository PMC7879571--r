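# Pedigree-based additive relationship matrices: tabular A, Meuwissen-Luo
# inbreeding, Henderson's sparse A-inverse, and block extraction for the
# sire/maternal-grandsire matrix of the survival model.

#' Inbreeding coefficients from a pedigree
#'
#' Meuwissen & Luo style recursion on the generalised Cholesky decomposition
#' A = TDT'; unknown parents are treated as unrelated non-inbred founders.
#'
#' @param ped A pedigree (coerced with [as_pedigree()]).
#' @return Named numeric vector of inbreeding coefficients F.
#' @export
ped_inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  pi <- ped_index(ped)
  n <- nrow(ped)
  s <- pi$sire
  d <- pi$dam
  f <- numeric(n)
  dvec <- numeric(n)
  anc <- numeric(n)   # reused accumulator, reset per animal on touched set
  for (i in seq_len(n)) {
    fs <- if (is.na(s[i])) -1 else f[s[i]]
    fd <- if (is.na(d[i])) -1 else f[d[i]]
    dvec[i] <- 0.5 - 0.25 * (fs + fd)
    if (is.na(s[i]) || is.na(d[i])) {
      f[i] <- 0
      next
    }
    # collect the ancestor set of i by upward BFS, then accumulate the L row
    # in decreasing pedigree order over that set only
    set <- c(s[i], d[i])
    frontier <- set
    while (length(frontier)) {
      par <- c(s[frontier], d[frontier])
      par <- unique(par[!is.na(par)])
      frontier <- par[!(par %in% set)]
      set <- c(set, frontier)
    }
    set <- sort(unique(set), decreasing = TRUE)
    anc[s[i]] <- anc[s[i]] + 0.5
    anc[d[i]] <- anc[d[i]] + 0.5
    fi <- 0
    for (j in set) {
      aj <- anc[j]
      if (aj == 0) next
      fi <- fi + aj * aj * dvec[j]
      if (!is.na(s[j])) anc[s[j]] <- anc[s[j]] + 0.5 * aj
      if (!is.na(d[j])) anc[d[j]] <- anc[d[j]] + 0.5 * aj
    }
    anc[set] <- 0
    f[i] <- fi + dvec[i] - 1   # a_ii = sum_j L_ij^2 d_j = 1 + F_i
  }
  setNames(f, pi$id)
}

# Mendelian-sampling variances d_i given parent indices and inbreeding
mendelian_d <- function(s, d, f) {
  fs <- ifelse(is.na(s), -1, f[ifelse(is.na(s), 1L, s)])
  fd <- ifelse(is.na(d), -1, f[ifelse(is.na(d), 1L, d)])
  0.5 - 0.25 * (fs + fd)
}

#' Additive relationship matrix A by the tabular method
#'
#' \eqn{a_{ii} = 1 + \tfrac12 a_{sd}}, \eqn{a_{ij} = \tfrac12 (a_{j,s(i)} +
#' a_{j,d(i)})}; an unknown parent contributes 0. Dense; intended for
#' pedigrees up to a few thousand animals (the sparse inverse covers the
#' production scale).
#'
#' @param ped A pedigree.
#' @return Dense symmetric matrix with dimnames the animal ids, carrying
#'   attribute `is_inverse = FALSE`.
#' @export
build_A <- function(ped) {
  ped <- as_pedigree(ped)
  pi <- ped_index(ped)
  n <- nrow(ped)
  s <- pi$sire
  d <- pi$dam
  A <- matrix(0, n, n, dimnames = list(pi$id, pi$id))
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    row <- numeric(i - 1L)
    if (!is.na(s[i])) row <- row + 0.5 * A[s[i], prev]
    if (!is.na(d[i])) row <- row + 0.5 * A[d[i], prev]
    if (i > 1L) {
      A[i, prev] <- row
      A[prev, i] <- row
    }
    asd <- if (!is.na(s[i]) && !is.na(d[i])) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
  }
  attr(A, "is_inverse") <- FALSE
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules, with Meuwissen-Luo inbreeding coefficients entering the
#' Mendelian-sampling variances when `with_inbreeding` is `TRUE`.
#'
#' @param ped A pedigree.
#' @param with_inbreeding Account for inbreeding in the Mendelian-sampling
#'   variances (exact A-inverse); `FALSE` gives the classical approximation
#'   that ignores inbreeding.
#' @return Sparse symmetric `Matrix` with dimnames the animal ids and
#'   attribute `is_inverse = TRUE`.
#' @export
build_A_inverse <- function(ped, with_inbreeding = TRUE) {
  ped <- as_pedigree(ped)
  pi <- ped_index(ped)
  n <- nrow(ped)
  s <- pi$sire
  d <- pi$dam
  f <- if (with_inbreeding) ped_inbreeding(ped) else numeric(n)
  dvec <- mendelian_d(s, d, f)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  push <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (i in seq_len(n)) {
    ai <- 1 / dvec[i]
    push(i, i, ai)
    par <- c(s[i], d[i])
    par <- par[!is.na(par)]
    for (p in par) {
      push(i, p, -0.5 * ai)
      push(p, i, -0.5 * ai)
    }
    if (length(par)) {
      for (p in par) for (q in par) push(p, q, 0.25 * ai)
    }
  }
  Ainv <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(pi$id, pi$id))
  Ainv <- forceSymmetric(Ainv)
  attr(Ainv, "is_inverse") <- TRUE
  Ainv
}

#' Relationship matrix among a subset of animals, from the full pedigree
#'
#' Computes the block of A for `ids` without forming the full dense A, via the
#' decomposition A = TDT' and sparse triangular solves. This is how the
#' relationship matrix among the stallions of the survival analysis (sires and
#' maternal grandsires) is obtained: the block is computed from the complete
#' pedigree, not from a males-only pedigree.
#'
#' @param ped The full pedigree.
#' @param ids Animals to keep (e.g. all sires and maternal grandsires).
#' @return Dense symmetric matrix over `ids` (in the order given).
#' @export
sire_mgs_matrix <- function(ped, ids) {
  ped <- as_pedigree(ped)
  pi <- ped_index(ped)
  ids <- as.character(ids)
  if (!all(ids %in% pi$id)) {
    abort(paste("ids absent from pedigree:",
                paste(setdiff(ids, pi$id), collapse = ", ")))
  }
  n <- nrow(ped)
  s <- pi$sire
  d <- pi$dam
  f <- ped_inbreeding(ped)
  dvec <- mendelian_d(s, d, f)
  rows <- c(seq_len(n), which(!is.na(s)), which(!is.na(d)))
  cols <- c(seq_len(n), s[!is.na(s)], d[!is.na(d)])
  vals <- c(rep(1, n), rep(-0.5, sum(!is.na(s))), rep(-0.5, sum(!is.na(d))))
  Tinv <- sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  k <- match(ids, pi$id)
  E <- sparseMatrix(i = k, j = seq_along(k), dims = c(n, length(k)))
  W <- as.matrix(solve(Matrix::t(Tinv), E))       # W = T' E
  out <- crossprod(W, dvec * W)
  out <- as.matrix(out)
  dimnames(out) <- list(ids, ids)
  attr(out, "is_inverse") <- FALSE
  out
}
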