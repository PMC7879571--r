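# Reduction of raw repeated gait measurements to per-horse adjusted effects,
# per-gait PCA, and per-recording principal-component scores.

#' Per-horse adjusted effects for each gait variable
#'
#' For each variable within a gait, fits a single-variable mixed model with
#' fixed effects of gender, age, event, recording type and the velocity
#' covariate (omitted when the response is velocity itself), plus an
#' independent random horse effect, and returns the BLUP of the horse
#' effect.
#'
#' @param measurements Long tibble from e.g. [simulate_gait_measurements()]:
#'   columns `horse`, `event_id`, `gait`, `recording_type`, `variable`,
#'   `value`, `velocity`, `gender`, `age`.
#' @return Tibble `horse`, `gait`, `variable`, `effect` (one row per horse
#'   per variable).
#' @export
estimate_horse_effects <- function(measurements) {
  check_columns(measurements,
                c("horse", "event_id", "gait", "recording_type", "variable",
                  "value", "velocity", "gender", "age"), "gait measurements")
  measurements %>%
    group_by(.data$gait, .data$variable) %>%
    dplyr::group_modify(function(df, key) {
      df$horse_f <- factor(df$horse)
      terms <- c(
        if (dplyr::n_distinct(df$gender) > 1) "gender",
        if (dplyr::n_distinct(df$age) > 1) "factor(age)",
        if (dplyr::n_distinct(df$event_id) > 1) "factor(event_id)",
        if (dplyr::n_distinct(df$recording_type) > 1) "recording_type",
        if (key$variable != "velocity" && sd(df$velocity) > 0) "velocity"
      )
      rhs <- paste(c(terms, "(1 | horse_f)"), collapse = " + ")
      fit <- suppressMessages(lme4::lmer(
        stats::as.formula(paste("value ~", rhs)), data = df,
        control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                    check.nobs.vs.nRE = "ignore")))
      re <- lme4::ranef(fit)$horse_f
      tibble(horse = df$horse[match(rownames(re), as.character(df$horse_f))],
             effect = re[[1]])
    }) %>%
    ungroup()
}

#' Principal component analysis of the per-horse gait effects
#'
#' Standardises each variable, eigendecomposes the correlation matrix, and
#' retains the leading components. The sign of each component is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param effects Output of [estimate_horse_effects()] for one gait (or a
#'   wide horses-by-variables matrix/data frame).
#' @param n_components Components to retain (study choice: 3 per gait).
#' @return A `gait_pca` object: `center`, `scale`, `loadings`
#'   (variables x components, orthonormal), `var_explained`, `scores`
#'   (tibble of per-horse scores), `eigenvalues`.
#' @export
pca_per_gait <- function(effects, n_components = 3L) {
  if (is_tibble(effects) && "variable" %in% names(effects)) {
    wide <- effects %>%
      select("horse", "variable", "effect") %>%
      tidyr::pivot_wider(names_from = "variable", values_from = "effect")
    X <- as.matrix(wide[-1])
    rownames(X) <- as.character(wide$horse)
  } else {
    X <- as.matrix(effects)
  }
  if (nrow(X) < ncol(X)) warn("fewer horses than variables: PCA is rank-deficient")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) abort("constant gait variable; cannot standardise")
  Z <- scale(X, center = ctr, scale = scl)
  ev <- eigen(stats::cor(X), symmetric = TRUE)
  k <- min(n_components, ncol(X))
  L <- ev$vectors[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    if (L[which.max(abs(L[, c])), c] < 0) L[, c] <- -L[, c]
  }
  dimnames(L) <- list(colnames(X), paste0("PC", seq_len(k)))
  scores <- Z %*% L
  structure(list(
    center = ctr, scale = scl, loadings = L,
    eigenvalues = ev$values,
    var_explained = ev$values[seq_len(k)] / sum(ev$values),
    scores = as_tibble(scores) %>% mutate(horse = rownames(X), .before = 1)
  ), class = "gait_pca")
}

#' @export
print.gait_pca <- function(x, ...) {
  cat(sprintf("<gait_pca> %d variables, %d components (%.1f%% of variance)\n",
              nrow(x$loadings), ncol(x$loadings),
              100 * sum(x$var_explained)))
  print(round(x$loadings, 2))
  invisible(x)
}

#' Project individual recordings onto the retained components
#'
#' Applies the standardisation and loadings learnt on the per-horse effects
#' to each working/medium recording, yielding up to two records per horse
#' per trot/canter component (one for walk) for the repeated-records
#' genetic analysis. Recordings are first adjusted for the same fixed
#' effects used in [estimate_horse_effects()] when `adjust` is supplied.
#'
#' @param measurements Long measurement tibble (one gait).
#' @param model A [pca_per_gait()] model for that gait.
#' @param adjust Optional tibble of per-record adjustments (columns `horse`,
#'   `recording_type`, `variable`, `adjusted`); defaults to centring raw
#'   values on the per-variable recording means.
#' @return Tibble `horse`, `recording_type`, one column per component;
#'   recordings missing any variable are withheld with a warning.
#' @export
pc_scores_per_recording <- function(measurements, model, adjust = NULL) {
  stopifnot(inherits(model, "gait_pca"))
  vars <- rownames(model$loadings)
  wide <- measurements %>%
    filter(.data$variable %in% vars) %>%
    select("horse", "recording_type", "variable", "value") %>%
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  complete <- stats::complete.cases(wide[vars])
  if (any(!complete)) {
    warn(sprintf("%d recording(s) missing a variable; scores withheld",
                 sum(!complete)))
    wide <- wide[complete, ]
  }
  X <- as.matrix(wide[vars])
  # recording-level centring: same scale as the horse-effect PCA, centred on
  # the recording means so a recording at the means scores 0
  Z <- scale(X, center = colMeans(X), scale = model$scale[vars])
  S <- Z %*% model$loadings
  bind_rows(tibble(horse = wide$horse, recording_type = wide$recording_type),
            .id = NULL) %>%
    dplyr::bind_cols(as_tibble(S))
}
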