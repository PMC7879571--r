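# Performance-level class system for the hazard model: the time-varying
# covariate that measures success net of which the model defines *functional*
# longevity.

#' Performance-level class specification
#'
#' Career-year-specific binning rules: year 1 uses gender alone (3 classes);
#' year 2 crosses gender with 8 z-score bins of the previous year's
#' log-points ("-2 and lower" to "+1.0 and higher" by steps of 0.5; 24
#' classes); year 3 adds a no-points class (27); from year 4 the z-range
#' widens to +/-2 (10 bins, plus no-points; 33 classes). Total: 87 distinct
#' classes. Bins are right-closed, so z = 0 falls in "(-0.5,0]".
#'
#' @param genders Gender codes (3 levels).
#' @return A `perf_level_spec` list with the per-year break vectors and the
#'   full 87-level factor level set.
#' @export
performance_level_spec <- function(genders = c("F", "M", "G")) {
  br2 <- c(-Inf, seq(-2, 1, by = 0.5), Inf)    # 8 bins
  br4 <- c(-Inf, seq(-2, 2, by = 0.5), Inf)    # 10 bins
  lab <- function(breaks) levels(cut(0, breaks, right = TRUE))
  lv <- c(
    paste0("y1:", genders),
    as.vector(outer(genders, lab(br2), function(g, b) paste0("y2:", g, ":", b))),
    as.vector(outer(genders, c(lab(br2), "none"),
                    function(g, b) paste0("y3:", g, ":", b))),
    as.vector(outer(genders, c(lab(br4), "none"),
                    function(g, b) paste0("y4+:", g, ":", b)))
  )
  structure(list(genders = genders, breaks_y2 = br2, breaks_y4 = br4,
                 levels = lv),
            class = "perf_level_spec")
}

#' Number of distinct performance-level classes
#' @param spec A [performance_level_spec()].
#' @return Integer count (87 for the default spec).
#' @export
n_performance_levels <- function(spec = performance_level_spec()) {
  length(spec$levels)
}

#' Assign performance-level classes to horse-year records
#'
#' The class for career year \eqn{j \ge 2} is determined by the z-score of
#' the log-transformed points the horse earned the *previous* year,
#' standardised within the study population per calendar year, crossed with
#' gender. Year-1 records are classed by gender alone; from year 3 a
#' "no points last year" class exists (`NA` previous points).
#'
#' @param career Tibble with columns `horse`, `year` (career index),
#'   `calendar_year`, `gender`, `points` (log-scale points earned that year;
#'   `NA` = no points).
#' @param spec A [performance_level_spec()].
#' @param standardise Standardise previous-year points within calendar year
#'   (set `FALSE` if `points` are already z-scores).
#' @return The input with a `perf_level` factor column (all 87 levels).
#' @export
build_performance_levels <- function(career, spec = performance_level_spec(),
                                     standardise = TRUE) {
  check_columns(career, c("horse", "year", "calendar_year", "gender", "points"),
                "career records")
  if (!all(career$gender %in% spec$genders)) {
    abort("career genders outside the specification's gender codes")
  }
  career <- career %>% arrange(.data$horse, .data$year)
  career <- career %>%
    group_by(.data$horse) %>%
    mutate(prev_points = dplyr::lag(.data$points),
           prev_cal = dplyr::lag(.data$calendar_year)) %>%
    ungroup()
  bad <- career$year == 1 & !is.na(career$prev_points)
  if (any(bad)) abort("year-1 records cannot carry previous-year points")
  if (standardise) {
    career <- career %>%
      group_by(.data$prev_cal) %>%
      mutate(z = as.numeric(scale(.data$prev_points))) %>%
      ungroup()
    career$z[is.na(career$prev_points)] <- NA
  } else {
    career$z <- career$prev_points
  }
  bin <- function(z, breaks) {
    out <- as.character(cut(z, breaks, right = TRUE))
    out[is.na(z)] <- "none"
    out
  }
  career <- career %>%
    mutate(perf_level = case_when(
      .data$year == 1 ~ paste0("y1:", .data$gender),
      .data$year == 2 ~ paste0("y2:", .data$gender, ":",
                               bin(.data$z, spec$breaks_y2)),
      .data$year == 3 ~ paste0("y3:", .data$gender, ":",
                               bin(.data$z, spec$breaks_y2)),
      TRUE ~ paste0("y4+:", .data$gender, ":", bin(.data$z, spec$breaks_y4))
    ))
  unknown <- setdiff(unique(career$perf_level), spec$levels)
  if (length(unknown)) {
    abort(paste("records map outside the class system:",
                paste(utils::head(unknown, 5), collapse = "; ")))
  }
  career$perf_level <- factor(career$perf_level, levels = spec$levels)
  career %>% select(-"prev_points", -"prev_cal", -"z")
}
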