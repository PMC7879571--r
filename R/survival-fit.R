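# Discrete-time proportional-hazards model of years in competition with
# correlated sire + maternal-grandsire random effects.
#
# Hazard: lambda(t_j, z_i) = 1 - alpha_j^{exp(eta_i)},
# eta_i = z_i' beta + u_{sire(i)} + 0.5 u_{mgs(i)}, u ~ N(0, A sigma_s^2).
# Writing alpha_j = exp(-exp(gamma_j)), each horse-year is a Bernoulli
# observation with a complementary-log-log link and linear predictor
# gamma_j + eta_i, which is what the Newton iterations below exploit.

#' Log-likelihood of career records under a discrete-time hazard model
#'
#' Survived years (status `continued` or `censored`) contribute
#' \eqn{e^{\eta} \log \alpha_j}; the event year contributes
#' \eqn{\log(1 - \alpha_j^{e^{\eta}})}.
#'
#' @param data Tibble with columns `year` and `status`.
#' @param alpha Baseline per-year survival probabilities (recycled).
#' @param eta Linear predictor per record (recycled).
#' @return Scalar log-likelihood.
#' @export
survival_loglik <- function(data, alpha, eta = 0) {
  check_columns(data, c("year", "status"), "career records")
  if (any(alpha <= 0 | alpha >= 1)) abort("alpha must lie strictly in (0,1)")
  a <- alpha[pmin(data$year, length(alpha))]
  e <- exp(rep_len(eta, nrow(data)))
  ll <- ifelse(data$status == "event",
               log1p(-a^e),
               e * log(a))
  if (any(!is.finite(ll))) {
    abort(sprintf("non-finite likelihood contribution at record %d",
                  which(!is.finite(ll))[1]))
  }
  sum(ll)
}

#' Fit the discrete-time survival model
#'
#' Joint posterior mode in (baseline, fixed effects, sire/MGS effects) for a
#' given sire variance by Newton iterations; the sire variance itself
#' maximises the Laplace-approximate marginal posterior over a grid followed
#' by golden-section refinement on \eqn{\log \sigma_s^2}. Prediction-error
#' variances come from the diagonal of the inverse negative Hessian at the
#' mode.
#'
#' @param data Career records: columns `horse`, `year`, `status`, `sire`
#'   (id or `NA`), optionally `mgs`, plus any class covariates named in
#'   `fixed`.
#' @param A Relationship matrix among the sires/MGS (from
#'   [sire_mgs_matrix()]); `NULL` treats them as unrelated.
#' @param fixed Character vector of column names entering as fixed class
#'   effects (first level of each is the reference).
#' @param sigma_grid Grid of candidate sire variances for the marginal
#'   search.
#' @param sigma_fixed Skip the variance search and fit at this value.
#' @param max_baseline Pool career years beyond this index into one baseline
#'   class (default: last year with an event).
#' @param max_iter,tol Newton iteration controls.
#' @return A `survival_fit` object: baseline table, fixed-effect table with
#'   risk ratios, EBV table (`id`, `ebv`, `pev`, `reliability`), `sigma_s2`,
#'   `h2`, uncensored proportion `p`, profile of the marginal posterior, and
#'   a `converged` flag (non-convergence is always explicit).
#' @export
fit_survival <- function(data, A = NULL, fixed = character(),
                         sigma_grid = c(0.005, 0.01, 0.02, 0.04, 0.08, 0.16),
                         sigma_fixed = NULL, max_baseline = NULL,
                         max_iter = 50L, tol = 1e-10) {
  check_columns(data, c("horse", "year", "status"), "career records")
  if (!"sire" %in% names(data)) data$sire <- NA
  if (!"mgs" %in% names(data)) data$mgs <- NA
  for (cn in fixed) check_columns(data, cn, "career records")

  max_baseline <- max_baseline %||% max(data$year[data$status == "event"], 1L)
  jcap <- pmin(data$year, max_baseline)
  y <- as.integer(data$status == "event")

  sires <- sort(unique(stats::na.omit(c(as.character(data$sire),
                                        as.character(data$mgs)))))
  q <- length(sires)
  if (q && !is.null(A)) {
    if (!all(sires %in% rownames(A))) {
      abort("relationship matrix A must cover every sire and MGS in the data")
    }
    A <- A[sires, sires, drop = FALSE]
  }

  # aggregate identical model rows (baseline class x covariates x parents x
  # outcome); the likelihood only sees counts
  keydf <- tibble(j = jcap, y = y,
                  sire = as.character(data$sire), mgs = as.character(data$mgs))
  for (cn in fixed) keydf[[cn]] <- as.character(data[[cn]])
  agg <- keydf %>%
    group_by(dplyr::across(dplyr::everything())) %>%
    summarise(n = dplyr::n(), .groups = "drop")

  nr <- nrow(agg)
  B <- sparseMatrix(i = seq_len(nr), j = agg$j, dims = c(nr, max_baseline))
  Xs <- list()
  fixed_terms <- list()
  for (cn in fixed) {
    f <- factor(agg[[cn]])
    if (nlevels(f) > 1) {
      Xs[[cn]] <- sparseMatrix(i = which(as.integer(f) > 1),
                               j = as.integer(f)[as.integer(f) > 1] - 1L,
                               dims = c(nr, nlevels(f) - 1L))
      fixed_terms[[cn]] <- tibble(term = cn, level = levels(f)[-1])
    }
  }
  X <- if (length(Xs)) do.call(cbind, Xs) else
    sparseMatrix(i = integer(0), j = integer(0), dims = c(nr, 0))
  fixed_terms <- bind_rows(fixed_terms)
  if (q) {
    si <- match(agg$sire, sires)
    mi <- match(agg$mgs, sires)
    Zi <- c(which(!is.na(si)), which(!is.na(mi)))
    Zj <- c(si[!is.na(si)], mi[!is.na(mi)])
    Zx <- c(rep(1, sum(!is.na(si))), rep(0.5, sum(!is.na(mi))))
    Z <- sparseMatrix(i = Zi, j = Zj, x = Zx, dims = c(nr, q))
  } else {
    Z <- sparseMatrix(i = integer(0), j = integer(0), dims = c(nr, 0))
  }
  W <- cbind(B, X, Z)
  p_fix <- ncol(B) + ncol(X)
  npar <- p_fix + q
  Ainv_s <- if (q) {
    if (is.null(A)) Diagonal(q) else {
      Ai <- tryCatch(solve(Matrix(A)), error = function(e) {
        abort("relationship matrix among sires is singular")
      })
      forceSymmetric(Matrix(Ai, sparse = TRUE))
    }
  } else NULL
  wts <- agg$n
  yv <- agg$y

  # penalized cloglog Newton at fixed sigma2; returns mode, Hessian, loglik
  inner_fit <- function(sigma2, start = NULL) {
    theta <- start %||% c(rep(log(-log(0.85)), ncol(B)), rep(0, ncol(X) + q))
    P <- Diagonal(npar, 1e-8)
    if (q) {
      iu <- seq.int(p_fix + 1L, npar)
      P[iu, iu] <- P[iu, iu] + Ainv_s / sigma2
    }
    ll_pen <- -Inf
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      psi <- as.numeric(W %*% theta)
      mu <- exp(pmin(psi, 30))
      qs <- exp(-mu)
      om <- -expm1(-mu)                  # 1 - exp(-mu)
      ll <- sum(wts * ifelse(yv == 1, log(pmax(om, 1e-300)), -mu))
      pen <- if (q) {
        u <- theta[seq.int(p_fix + 1L, npar)]
        -0.5 * as.numeric(u %*% (Ainv_s %*% u)) / sigma2
      } else 0
      new_pen <- ll + pen - 0.5e-8 * sum(theta^2)
      g1 <- ifelse(yv == 1, mu * qs / pmax(om, 1e-300), -mu)
      h1 <- ifelse(yv == 1,
                   mu * qs / pmax(om, 1e-300) - mu^2 * qs / pmax(om, 1e-300)^2,
                   -mu)
      grad <- as.numeric(Matrix::t(W) %*% (wts * g1)) - as.numeric(P %*% theta)
      H <- Matrix::t(W) %*% Diagonal(nr, -wts * h1) %*% W + P
      delta <- tryCatch(as.numeric(solve(H, grad)), error = function(e) NULL)
      if (is.null(delta)) break
      step <- 1
      repeat {
        cand <- theta + step * delta
        psi_c <- as.numeric(W %*% cand)
        mu_c <- exp(pmin(psi_c, 30))
        om_c <- -expm1(-mu_c)
        ll_c <- sum(wts * ifelse(yv == 1, log(pmax(om_c, 1e-300)), -mu_c))
        pen_c <- if (q) {
          u <- cand[seq.int(p_fix + 1L, npar)]
          -0.5 * as.numeric(u %*% (Ainv_s %*% u)) / sigma2
        } else 0
        cand_pen <- ll_c + pen_c - 0.5e-8 * sum(cand^2)
        if (cand_pen >= new_pen - 1e-12 || step < 1e-4) break
        step <- step / 2
      }
      theta <- theta + step * delta
      conv <- abs(cand_pen - ll_pen) < tol * (abs(cand_pen) + 1)
      ll_pen <- cand_pen
      if (conv) {
        ok <- TRUE
        break
      }
    }
    psi <- as.numeric(W %*% theta)
    mu <- exp(pmin(psi, 30))
    qs <- exp(-mu)
    om <- -expm1(-mu)
    h1 <- ifelse(yv == 1,
                 mu * qs / pmax(om, 1e-300) - mu^2 * qs / pmax(om, 1e-300)^2,
                 -mu)
    P <- Diagonal(npar, 1e-8)
    if (q) {
      iu <- seq.int(p_fix + 1L, npar)
      P[iu, iu] <- P[iu, iu] + Ainv_s / sigma2
    }
    H <- Matrix::t(W) %*% Diagonal(nr, -wts * h1) %*% W + P
    ll <- sum(wts * ifelse(yv == 1, log(pmax(om, 1e-300)), -mu))
    list(theta = theta, H = H, loglik = ll, converged = ok)
  }

  # Laplace-approximate log marginal posterior of sigma2
  marginal <- function(sigma2, start = NULL) {
    f <- inner_fit(sigma2, start)
    u <- if (q) f$theta[seq.int(p_fix + 1L, npar)] else numeric(0)
    pen <- if (q) -0.5 * as.numeric(u %*% (Ainv_s %*% u)) / sigma2 else 0
    ch <- Cholesky(forceSymmetric(f$H), LDL = FALSE, perm = TRUE)
    logdet <- 2 * sum(log(Matrix::diag(as(ch, "Matrix"))))
    lm <- f$loglik + pen - 0.5 * q * log(sigma2) - 0.5 * logdet
    list(lm = lm, fit = f)
  }

  profile <- NULL
  if (!q || !is.null(sigma_fixed)) {
    sigma2 <- sigma_fixed %||% 0
    best <- if (q) marginal(sigma2) else list(fit = inner_fit(1), lm = NA)
    fitq <- best$fit
  } else {
    evals <- map(sigma_grid, function(s2) marginal(s2))
    lms <- map_dbl(evals, "lm")
    profile <- tibble(sigma2 = sigma_grid, log_marginal = lms)
    k <- which.max(lms)
    lo <- log(sigma_grid[max(k - 1, 1)])
    hi <- log(sigma_grid[min(k + 1, length(sigma_grid))])
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- marginal(exp(x1))$lm; f2 <- marginal(exp(x2))$lm
    for (i in seq_len(25)) {
      if (b - a < 1e-3) break
      if (f1 < f2) {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- marginal(exp(x2))$lm
      } else {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- marginal(exp(x1))$lm
      }
    }
    sigma2 <- exp((a + b) / 2)
    best <- marginal(sigma2)
    fitq <- best$fit
    profile <- bind_rows(profile,
                         tibble(sigma2 = sigma2, log_marginal = best$lm)) %>%
      arrange(.data$sigma2)
  }

  theta <- fitq$theta
  gamma <- theta[seq_len(ncol(B))]
  beta <- if (ncol(X)) theta[seq.int(ncol(B) + 1L, p_fix)] else numeric(0)

  # prediction-error variances and fixed-effect SEs from the inverse Hessian
  Cdiag <- tryCatch({
    ch <- Cholesky(forceSymmetric(fitq$H), LDL = FALSE, perm = TRUE)
    inv <- solve(ch, Diagonal(npar))
    Matrix::diag(inv)
  }, error = function(e) rep(NA_real_, npar))

  ebv <- if (q) {
    u <- theta[seq.int(p_fix + 1L, npar)]
    pev <- Cdiag[seq.int(p_fix + 1L, npar)]
    tibble(id = sires, ebv = u, pev = pev,
           reliability = reliability(pev, sigma2))
  } else tibble(id = character(0), ebv = numeric(0), pev = numeric(0),
                reliability = numeric(0))

  horses_last <- data %>% filter(.data$status != "continued")
  p_unc <- mean(horses_last$status == "event")
  fixed_tbl <- if (nrow(fixed_terms)) {
    fixed_terms %>%
      mutate(estimate = beta,
             se = sqrt(Cdiag[seq.int(ncol(B) + 1L, p_fix)]),
             risk_ratio = risk_ratio(beta))
  } else {
    tibble(term = character(0), level = character(0), estimate = numeric(0),
           se = numeric(0), risk_ratio = numeric(0))
  }
  structure(list(
    baseline = tibble(year = seq_len(max_baseline), gamma = gamma,
                      alpha = exp(-exp(gamma))),
    fixed = fixed_tbl,
    ebv = ebv,
    sigma_s2 = if (q) sigma2 else 0,
    p_uncensored = p_unc,
    h2 = if (q) heritability_sire(sigma2, p_unc) else 0,
    loglik = fitq$loglik,
    log_marginal = best$lm,
    profile = profile,
    converged = fitq$converged,
    n_records = nrow(data),
    n_horses = dplyr::n_distinct(data$horse)
  ), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("<survival_fit> discrete-time proportional-hazards sire-MGS model\n")
  cat(sprintf("  %d records, %d horses, %d sires | converged: %s\n",
              x$n_records, x$n_horses, nrow(x$ebv), x$converged))
  cat(sprintf("  sigma_s2 = %.5f | p(uncensored) = %.3f | h2 = %.3f\n",
              x$sigma_s2, x$p_uncensored, x$h2))
  invisible(x)
}

#' Sire-model heritability on the survival scale
#'
#' \eqn{h^2 = 4\sigma_s^2 / (\sigma_s^2 + 1/p)} with `p` the proportion of
#' uncensored records.
#'
#' @param sigma_s2 Sire variance (log-hazard scale).
#' @param p Proportion of uncensored records, in (0, 1].
#' @return Heritability.
#' @export
#' @examples
#' heritability_sire(0.03947, 0.78)
heritability_sire <- function(sigma_s2, p) {
  if (sigma_s2 < 0) abort("`sigma_s2` must be non-negative")
  if (any(p <= 0) || any(p > 1)) abort("`p` must lie in (0, 1]")
  4 * sigma_s2 / (sigma_s2 + 1 / p)
}

#' Risk ratio of a hazard-model coefficient
#'
#' @param beta Log-hazard coefficient (reference class has beta = 0).
#' @return `exp(beta)`, the multiplicative change in culling risk.
#' @export
risk_ratio <- function(beta) exp(beta)
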