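# Bivariate linear mixed model joining one gait trait (individual level,
# repeated records, permanent environment) with longevity pseudo-phenotypes
# (sire level, weighted residuals) under a single relationship matrix H:
#
#   y  = X b + Z u  + W p + e      R  = I sigma_e^2  (p absorbed: 2x2 blocks)
#   y* =       Z* u*       + e*    R* = D sigma_e*^2,  D = diag(1/w)
#   V[u, u*] = G (2x2) kron H
#
# The longevity components sigma_u*^2 and sigma_e*^2 are fixed (they are
# better estimated by the survival analysis); the gait variances and the
# genetic covariance are estimated by REML. The restricted log-likelihood is
# evaluated exactly through one sparse Cholesky factorisation of the
# mixed-model equations per evaluation,
#   -2 logL_R = log|R| + log|G kron H| + log|C| + y'Py,
# and maximised by quasi-Newton iterations on transformed coordinates
# (log-variances, atanh correlation); standard errors come from the observed
# information on the original coordinates.

#' Specification of the bi-trait model
#'
#' @param fixed Class-effect column names for the gait trait (those present
#'   in the data are used; first level is the reference).
#' @param covariates Numeric covariate column names for the gait trait.
#' @param sigma_u_star2 Fixed genetic variance of longevity (sire scale).
#' @param sigma_e_star2 Fixed residual scale of longevity; a record with
#'   weight w has residual variance `sigma_e_star2 / w`.
#' @return A `bitrait_spec` list.
#' @export
bitrait_spec <- function(fixed = c("event_id", "gender", "age"),
                         covariates = c("velocity", "height"),
                         sigma_u_star2 = 0.03947,
                         sigma_e_star2 = NULL) {
  # default residual scale keeps the pseudo-phenotype weights coherent with
  # lambda = (1 - h2)/h2 at the survival-analysis heritability
  if (is.null(sigma_e_star2)) {
    h2 <- heritability_sire(sigma_u_star2, 0.78)
    sigma_e_star2 <- (1 - h2) / h2 * sigma_u_star2
  }
  structure(list(fixed = fixed, covariates = covariates,
                 sigma_u_star2 = sigma_u_star2,
                 sigma_e_star2 = sigma_e_star2),
            class = "bitrait_spec")
}

# Precompute the parameter-independent pieces of the MME for one dataset.
# gait: tibble with horse, value (+ design columns); longevity: id, y_star, w
# Hinv: sparse relationship inverse over all animals (dimnames = ids)
bitrait_structure <- function(gait, longevity, Hinv, spec) {
  ids <- rownames(Hinv)
  if (!is.null(gait)) {
    check_columns(gait, c("horse", "value"), "gait records")
    if (!all(as.character(gait$horse) %in% ids)) {
      miss <- setdiff(unique(as.character(gait$horse)), ids)
      abort(paste("gait horses absent from H:",
                  paste(utils::head(miss, 5), collapse = ", ")))
    }
  }
  if (!is.null(longevity)) {
    check_columns(longevity, c("id", "y_star", "w"), "longevity records")
    if (any(longevity$w <= 0)) abort("longevity weights must be positive")
    if (!all(as.character(longevity$id) %in% ids)) {
      miss <- setdiff(as.character(longevity$id), ids)
      abort(paste("longevity sires absent from H:",
                  paste(utils::head(miss, 5), collapse = ", ")))
    }
  }
  nH <- length(ids)
  # gait design
  X <- NULL; Z1 <- NULL; y1 <- NULL; horse_rec <- NULL
  if (!is.null(gait) && nrow(gait)) {
    y1 <- gait$value
    n1 <- length(y1)
    cols <- list(`(Intercept)` = Matrix(1, n1, 1))
    for (cn in intersect(spec$fixed, names(gait))) {
      f <- factor(gait[[cn]])
      if (nlevels(f) > 1) {
        M <- sparseMatrix(i = which(as.integer(f) > 1),
                          j = as.integer(f)[as.integer(f) > 1] - 1L,
                          dims = c(n1, nlevels(f) - 1L))
        colnames(M) <- paste0(cn, levels(f)[-1])
        cols[[cn]] <- M
      }
    }
    for (cn in intersect(spec$covariates, names(gait))) {
      if (sd(gait[[cn]]) > 0) {
        cols[[cn]] <- Matrix(gait[[cn]] - mean(gait[[cn]]), n1, 1,
                             dimnames = list(NULL, cn))
      }
    }
    X <- do.call(cbind, cols)
    hi <- match(as.character(gait$horse), ids)
    Z1 <- sparseMatrix(i = seq_len(n1), j = hi, dims = c(n1, nH))
    horse_rec <- hi
  }
  Z2 <- NULL; y2 <- NULL; w2 <- NULL
  if (!is.null(longevity) && nrow(longevity)) {
    li <- match(as.character(longevity$id), ids)
    Z2 <- sparseMatrix(i = seq_along(li), j = li,
                       dims = c(length(li), nH))
    y2 <- longevity$y_star
    w2 <- longevity$w
  }
  ch_H <- Cholesky(forceSymmetric(Matrix(Hinv, sparse = TRUE)),
                   LDL = FALSE, perm = TRUE)
  logdet_H <- -2 * sum(log(Matrix::diag(as(ch_H, "Matrix"))))
  list(ids = ids, nH = nH, X = X, Z1 = Z1, y1 = y1, horse = horse_rec,
       Z2 = Z2, y2 = y2, w2 = w2, Hinv = forceSymmetric(Matrix(Hinv, sparse = TRUE)),
       logdet_H = logdet_H, spec = spec, cache = new.env(parent = emptyenv()))
}

# residual inverse for the gait trait: per-horse blocks (sigma_e2 I + sigma_pe2 J)^-1
gait_Rinv <- function(horse, sigma_e2, sigma_pe2) {
  n1 <- length(horse)
  split_idx <- split(seq_len(n1), horse)
  # closed form: (aI + bJ)^-1 = I/a - b/(a(a+rb)) J
  trip <- lapply(split_idx, function(rows) {
    r <- length(rows)
    offv <- -sigma_pe2 / (sigma_e2 * (sigma_e2 + r * sigma_pe2))
    M <- matrix(offv, r, r)
    diag(M) <- 1 / sigma_e2 + offv
    list(i = rep(rows, each = r), j = rep(rows, times = r), x = as.numeric(M))
  })
  sparseMatrix(i = unlist(lapply(trip, `[[`, "i"), use.names = FALSE),
               j = unlist(lapply(trip, `[[`, "j"), use.names = FALSE),
               x = unlist(lapply(trip, `[[`, "x"), use.names = FALSE),
               dims = c(n1, n1))
}

# log-determinant of the gait residual covariance
gait_logdet_R <- function(horse, sigma_e2, sigma_pe2) {
  r <- tabulate(factor(horse))
  sum((r - 1) * log(sigma_e2) + log(sigma_e2 + r * sigma_pe2))
}

#' Assemble the bi-trait mixed-model equations
#'
#' Henderson equations with trait-specific residual structures (gait:
#' per-horse compound-symmetry blocks absorbing the permanent environment;
#' longevity: diagonal `sigma_e_star2 / w`), the genetic (co)variance
#' entering through \eqn{G^{-1} \otimes H^{-1}}.
#'
#' @param str Structure from the internal builder (see [reml_bitrait()]), or
#'   the arguments of [reml_bitrait()] passed through `...`.
#' @param varcomp Named list/vector with `sigma_u2`, `sigma_pe2`,
#'   `sigma_e2`, `cov_u` (gait-longevity genetic covariance).
#' @param ... Passed to the structure builder when `str` is raw data.
#' @return List with `C` (coefficient matrix), `rhs`, `blocks` (index map)
#'   and the residual log-determinant pieces.
#' @export
build_bitrait_mme <- function(str, varcomp, ...) {
  if (!inherits(str, "bitrait_structure_built")) {
    args <- list(...)
    str <- bitrait_structure(str, args$longevity, args$Hinv, args$spec)
  }
  vc <- as.list(varcomp)
  spec <- str$spec
  has1 <- !is.null(str$y1)
  has2 <- !is.null(str$y2)
  G2 <- matrix(c(vc$sigma_u2, vc$cov_u %||% 0, vc$cov_u %||% 0,
                 spec$sigma_u_star2), 2, 2)
  p <- if (has1) ncol(str$X) else 0L
  nH <- str$nH
  blocks <- list(beta = seq_len(p),
                 u1 = p + seq_len(nH),
                 u2 = p + nH + seq_len(nH))
  # both genetic effects are always carried; a trait without data is tied in
  # only through G
  Gi <- solve(G2)
  C11 <- Gi[1, 1] * str$Hinv
  C22 <- Gi[2, 2] * str$Hinv
  C12 <- Gi[1, 2] * str$Hinv
  logdet_R <- 0
  rhs <- numeric(p + 2 * nH)
  if (has1) {
    R1i <- gait_Rinv(str$horse, vc$sigma_e2, vc$sigma_pe2 %||% 0)
    logdet_R <- logdet_R + gait_logdet_R(str$horse, vc$sigma_e2,
                                         vc$sigma_pe2 %||% 0)
    XR <- Matrix::t(str$X) %*% R1i
    ZR <- Matrix::t(str$Z1) %*% R1i
    Cbb <- XR %*% str$X
    Cb1 <- XR %*% str$Z1
    C11 <- C11 + ZR %*% str$Z1
    rhs[blocks$beta] <- as.numeric(XR %*% str$y1)
    rhs[blocks$u1] <- as.numeric(ZR %*% str$y1)
    yRy1 <- as.numeric(str$y1 %*% (R1i %*% str$y1))
  } else {
    Cbb <- NULL; Cb1 <- NULL; yRy1 <- 0
  }
  if (has2) {
    d2 <- str$w2 / spec$sigma_e_star2
    logdet_R <- logdet_R + sum(log(spec$sigma_e_star2 / str$w2))
    ZtD <- Matrix::t(str$Z2 * d2)
    C22 <- C22 + ZtD %*% str$Z2
    rhs[blocks$u2] <- as.numeric(ZtD %*% str$y2)
    yRy2 <- sum(str$y2^2 * d2)
  } else {
    yRy2 <- 0
  }
  if (p) {
    zero_p1 <- Matrix(0, p, nH, sparse = TRUE)
    C <- rbind(cbind(Cbb, Cb1, zero_p1),
               cbind(Matrix::t(Cb1), C11, C12),
               cbind(Matrix::t(zero_p1), Matrix::t(C12), C22))
  } else {
    C <- rbind(cbind(C11, C12), cbind(Matrix::t(C12), C22))
  }
  list(C = forceSymmetric(drop0(C)), rhs = rhs, blocks = blocks,
       logdet_R = logdet_R, yRy = yRy1 + yRy2,
       logdet_G = nH * determinant2x2_log(G2) + 2 * str$logdet_H,
       n_data = length(str$y1 %||% numeric(0)) + length(str$y2 %||% numeric(0)),
       p = p)
}

determinant2x2_log <- function(G) {
  d <- G[1, 1] * G[2, 2] - G[1, 2]^2
  if (d <= 0) return(-Inf)
  log(d)
}

# restricted log-likelihood (up to a constant); the symbolic factorisation
# is analysed once per dataset and reused across evaluations
bitrait_logLR <- function(str, vc) {
  mme <- build_bitrait_mme(structure(str, class = "bitrait_structure_built"), vc)
  if (!is.finite(mme$logdet_G)) return(list(ll = -Inf))
  cache <- str$cache
  ch <- if (!is.null(cache$ch)) {
    tryCatch(Matrix::update(cache$ch, mme$C), error = function(e) NULL)
  }
  if (is.null(ch)) {
    ch <- tryCatch(Cholesky(mme$C, LDL = FALSE, perm = TRUE, super = TRUE),
                   error = function(e) NULL)
    if (!is.null(ch) && !is.null(cache)) cache$ch <- ch
  }
  if (is.null(ch)) return(list(ll = -Inf))
  logdet_C <- as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                             sqrt = FALSE)$modulus)
  sol <- as.numeric(solve(ch, mme$rhs))
  yPy <- mme$yRy - sum(sol * mme$rhs)
  ll <- -0.5 * (mme$logdet_R + mme$logdet_G + logdet_C + yPy)
  list(ll = ll, sol = sol, mme = mme, ch = ch)
}

#' Constrained bivariate REML for one gait trait and longevity
#'
#' Estimates the gait genetic, permanent-environment and residual variances
#' and the gait-longevity genetic covariance by restricted maximum
#' likelihood, holding the longevity variance components fixed at the
#' survival-analysis values. Works single-trait (gait only) when
#' `longevity` is `NULL`, in which case the covariance is not estimated.
#'
#' Non-convergence is always declared, never silent: the fit carries
#' `converged = FALSE` with a reason when the optimiser fails, the observed
#' information is singular or indefinite, or the genetic variance collapses
#' to the boundary (where the genetic correlation is undefined).
#'
#' @param gait Gait records: `horse`, `value`, plus design columns named in
#'   the spec. Repeated records per horse give the permanent-environment
#'   component; single records fix it at 0.
#' @param longevity Pseudo-phenotypes: `id`, `y_star`, `w` (or `NULL`).
#' @param Hinv Sparse relationship inverse over all animals (pedigree
#'   [build_A_inverse()] or single-step [build_H_inverse()]).
#' @param spec A [bitrait_spec()].
#' @param start Optional named start values (`sigma_u2`, `sigma_pe2`,
#'   `sigma_e2`, `cov_u`); default: half the phenotypic variance to
#'   genetics, the rest split equally.
#' @param max_iter Maximum optimiser iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param compute_se Compute the observed information (standard errors,
#'   convergence diagnostics); skipping it speeds up replicate runs but
#'   weakens the non-convergence checks to optimiser status and boundary
#'   detection.
#' @return A `bitrait_reml` object; see [tidy.bitrait_reml()] and
#'   [derived_parameters()].
#' @export
reml_bitrait <- function(gait, longevity = NULL, Hinv, spec = bitrait_spec(),
                         start = NULL, max_iter = 200L, tol = 1e-8,
                         compute_se = TRUE) {
  str <- bitrait_structure(gait, longevity, Hinv, spec)
  has2 <- !is.null(str$y2)
  repeated <- !is.null(str$horse) && max(tabulate(factor(str$horse))) > 1
  vp <- var(str$y1)
  s0 <- start %||% list(sigma_u2 = vp / 2,
                        sigma_pe2 = if (repeated) vp / 4 else 0,
                        sigma_e2 = if (repeated) vp / 4 else vp / 2,
                        cov_u = if (has2) 0.01 * sqrt(vp * spec$sigma_u_star2) else 0)
  # transformed coordinates: log variances, atanh genetic correlation
  pack <- function(vc) {
    c(log(vc$sigma_u2),
      if (repeated) log(max(vc$sigma_pe2, 1e-10)),
      log(vc$sigma_e2),
      if (has2) atanh(max(min(vc$cov_u /
                                sqrt(vc$sigma_u2 * spec$sigma_u_star2),
                              0.999), -0.999)))
  }
  unpack <- function(par) {
    i <- 1
    vc <- list(sigma_u2 = exp(par[i]))
    i <- i + 1
    if (repeated) { vc$sigma_pe2 <- exp(par[i]); i <- i + 1 } else vc$sigma_pe2 <- 0
    vc$sigma_e2 <- exp(par[i]); i <- i + 1
    vc$cov_u <- if (has2) {
      tanh(par[i]) * sqrt(vc$sigma_u2 * spec$sigma_u_star2)
    } else 0
    vc
  }
  nll <- function(par) {
    vc <- unpack(par)
    r <- bitrait_logLR(str, vc)
    if (!is.finite(r$ll)) return(1e10)
    -r$ll
  }
  opt <- nlminb(pack(s0), nll,
                control = list(iter.max = max_iter, eval.max = 4L * max_iter,
                               rel.tol = tol))
  vc_hat <- unpack(opt$par)
  final <- bitrait_logLR(str, vc_hat)

  # observed information on the original (variance/covariance) coordinates
  free <- c("sigma_u2", if (repeated) "sigma_pe2", "sigma_e2",
            if (has2) "cov_u")
  theta <- unlist(vc_hat[free])
  nll_orig <- function(th) {
    vc <- vc_hat
    vc[free] <- as.list(th)
    if (vc$sigma_u2 <= 0 || vc$sigma_e2 <= 0 || vc$sigma_pe2 < 0) return(NA_real_)
    r <- bitrait_logLR(str, vc)
    if (!is.finite(r$ll)) NA_real_ else -r$ll
  }
  vcov_free <- NULL
  if (compute_se) {
    Hess <- numeric_hessian(nll_orig, theta)
    info_ok <- all(is.finite(Hess))
    if (info_ok) {
      ev <- eigen(Hess, symmetric = TRUE, only.values = TRUE)$values
      info_ok <- all(ev > 0) && min(ev) / max(ev) > 1e-10
      if (info_ok) vcov_free <- solve(Hess)
    }
  } else {
    info_ok <- TRUE
  }
  boundary <- vc_hat$sigma_u2 < 1e-5 * vp
  converged <- opt$convergence == 0 && info_ok && !boundary
  message <- if (opt$convergence != 0) {
    paste("optimiser did not converge:", opt$message)
  } else if (boundary) {
    "genetic variance collapsed to the boundary; genetic correlation undefined"
  } else if (!info_ok) {
    "observed information singular or indefinite; estimates not uniquely determined"
  } else "converged"
  if (!is.null(vcov_free)) dimnames(vcov_free) <- list(free, free)
  se <- if (!is.null(vcov_free)) sqrt(pmax(Matrix::diag(vcov_free), 0)) else
    rep(NA_real_, length(free))
  varcomp <- tibble(
    component = c(free, "sigma_u_star2", "sigma_e_star2"),
    estimate = c(unlist(vc_hat[free]), spec$sigma_u_star2, spec$sigma_e_star2),
    se = c(se, NA, NA),
    fixed = c(rep(FALSE, length(free)), TRUE, TRUE)
  )
  fit <- structure(list(
    varcomp = varcomp, vc = vc_hat, vcov = vcov_free, spec = spec,
    loglik = final$ll, converged = converged, message = message,
    boundary = boundary, repeated = repeated, bivariate = has2,
    n_gait = length(str$y1 %||% numeric(0)),
    n_longevity = length(str$y2 %||% numeric(0)),
    n_animals = str$nH, solutions = final$sol, blocks = final$mme$blocks,
    ids = str$ids, opt = opt
  ), class = "bitrait_reml")
  fit$derived <- derived_parameters(fit)
  fit
}

# central-difference Hessian with relative steps
numeric_hessian <- function(f, x, rel = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x), 1e-3) * rel
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        fp <- f(replace(x, i, x[i] + h[i]))
        fm <- f(replace(x, i, x[i] - h[i]))
        H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
      } else {
        fpp <- f(replace(replace(x, i, x[i] + h[i]), j, x[j] + h[j]))
        fpm <- f(replace(replace(x, i, x[i] + h[i]), j, x[j] - h[j]))
        fmp <- f(replace(replace(x, i, x[i] - h[i]), j, x[j] + h[j]))
        fmm <- f(replace(replace(x, i, x[i] - h[i]), j, x[j] - h[j]))
        H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Heritability, repeatability and genetic correlation from a fit
#'
#' \eqn{h^2 = \sigma_u^2 / (\sigma_u^2 + \sigma_{pe}^2 + \sigma_e^2)},
#' repeatability \eqn{= (\sigma_u^2 + \sigma_{pe}^2)} over the same
#' phenotypic variance, \eqn{r_g = \sigma_{uu^*} / \sqrt{\sigma_u^2
#' \sigma_{u^*}^2}}; standard errors by the delta method from the
#' component covariance matrix. Because longevity genetic values are on the
#' risk scale, a negative \eqn{r_g} means the gait trait favours longevity;
#' the table carries that interpretation flag.
#'
#' @param fit A `bitrait_reml` object (or a named list of components with a
#'   `vcov` attribute).
#' @return Tibble `parameter`, `estimate`, `se`, `interpretation`.
#' @export
derived_parameters <- function(fit) {
  vc <- fit$vc
  V <- fit$vcov
  phen <- vc$sigma_u2 + vc$sigma_pe2 + vc$sigma_e2
  if (phen <= 0) abort("zero phenotypic variance")
  su2s <- fit$spec$sigma_u_star2
  grad_se <- function(g, names_g) {
    if (is.null(V)) return(NA_real_)
    g_full <- setNames(numeric(ncol(V)), colnames(V))
    g_full[names_g] <- g
    sqrt(max(as.numeric(g_full %*% V %*% g_full), 0))
  }
  h2 <- vc$sigma_u2 / phen
  g_h2 <- c(sigma_u2 = (phen - vc$sigma_u2) / phen^2,
            sigma_pe2 = -vc$sigma_u2 / phen^2,
            sigma_e2 = -vc$sigma_u2 / phen^2)
  present <- intersect(names(g_h2), colnames(V) %||% character(0))
  out <- tibble(parameter = "h2", estimate = h2,
                se = grad_se(g_h2[present], present),
                interpretation = "gait trait heritability")
  if (fit$repeated) {
    rep_ <- (vc$sigma_u2 + vc$sigma_pe2) / phen
    g_rep <- c(sigma_u2 = (phen - (vc$sigma_u2 + vc$sigma_pe2)) / phen^2,
               sigma_pe2 = (phen - (vc$sigma_u2 + vc$sigma_pe2)) / phen^2,
               sigma_e2 = -(vc$sigma_u2 + vc$sigma_pe2) / phen^2)
    present <- intersect(names(g_rep), colnames(V) %||% character(0))
    out <- bind_rows(out, tibble(
      parameter = "repeatability", estimate = rep_,
      se = grad_se(g_rep[present], present),
      interpretation = "working/medium recordings repeat the same trait"))
  }
  if (fit$bivariate) {
    denom <- sqrt(vc$sigma_u2 * su2s)
    rg <- vc$cov_u / denom
    g_rg <- c(cov_u = 1 / denom,
              sigma_u2 = -0.5 * vc$cov_u / (denom * vc$sigma_u2))
    present <- intersect(names(g_rg), colnames(V) %||% character(0))
    out <- bind_rows(out, tibble(
      parameter = "r_g", estimate = rg,
      se = grad_se(g_rg[present], present),
      interpretation = paste("genetic correlation with the longevity risk",
                             "scale: negative = favours longevity")))
  }
  out
}

#' @export
print.bitrait_reml <- function(x, ...) {
  cat("<bitrait_reml>",
      if (x$bivariate) "gait x longevity" else "gait only",
      if (x$repeated) "with permanent environment" else "", "\n")
  cat(sprintf("  %d gait records, %d pseudo-phenotypes, %d animals in H\n",
              x$n_gait, x$n_longevity, x$n_animals))
  cat(sprintf("  logL_R = %.3f | %s\n", x$loglik, x$message))
  print(x$derived)
  invisible(x)
}
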