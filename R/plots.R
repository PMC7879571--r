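# ggplot2 displays for the main result types.

#' Manhattan plot of SNP-effect p-values
#'
#' @param table Output of [snp_pvalues()].
#' @param threshold Horizontal reference at this \eqn{-\log_{10} p}.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(table, threshold = 5) {
  check_columns(table, c("chr", "pos", "neg_log10_p"), "SNP table")
  df <- table %>%
    filter(!is.na(.data$neg_log10_p)) %>%
    mutate(chr_f = factor(.data$chr, levels = unique(.data$chr))) %>%
    arrange(.data$chr_f, .data$pos) %>%
    mutate(x = row_number())
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$neg_log10_p,
                                   colour = .data$chr_f)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "SNP (genome order)",
                  y = expression(-log[10](italic(P))),
                  title = "SNP effects on longevity") +
    ggplot2::theme_minimal()
}

#' @method autoplot survival_fit
#' @export
autoplot.survival_fit <- function(object, ...) {
  df <- object$baseline %>%
    mutate(surv = cumprod(.data$alpha))
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Career year", y = "Baseline survival S(t)",
                  title = "Fitted baseline survivor function") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @method autoplot gait_pca
#' @export
autoplot.gait_pca <- function(object, ...) {
  L <- object$loadings
  df <- tibble(
    variable = rep(rownames(L), ncol(L)),
    component = rep(colnames(L), each = nrow(L)),
    loading = as.numeric(L)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$loading, .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "Eigenvector loading", y = NULL,
                  title = "Per-gait principal components") +
    ggplot2::theme_minimal()
}

#' @method autoplot bitrait_reml
#' @export
autoplot.bitrait_reml <- function(object, ...) {
  df <- object$derived %>%
    mutate(lo = .data$estimate - 1.96 * .data$se,
           hi = .data$estimate + 1.96 * .data$se)
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = NULL, y = "Estimate (95% CI)",
                  title = "Genetic parameters") +
    ggplot2::theme_minimal()
}
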