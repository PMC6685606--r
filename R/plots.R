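#' Forest plot of causal-effect estimates
#'
#' Odds ratios with 95% CIs on a log-scaled axis, one row per estimate, with
#' the null line at OR = 1.
#'
#' @param estimates Estimate tibble (needs `beta`, `ci_low`, `ci_high` and a
#'   label column, by default `exposure`).
#' @param label Column used for the row labels.
#' @return A ggplot object.
#' @export
forest_plot <- function(estimates, label = "exposure") {
  stopifnot(nrow(estimates) >= 1)
  d <- tibble::tibble(
    label = factor(estimates[[label]], rev(unique(estimates[[label]]))),
    or = exp(estimates$beta),
    lo = exp(estimates$ci_low),
    hi = exp(estimates$ci_high)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of SNP effects with fitted causal slopes
#'
#' Exposure effects against outcome effects, one point per SNP (error bars at
#' one SE), overlaid with the fitted line of each supplied estimator (through
#' the origin for IVW/median/mode, with intercept for Egger).
#'
#' @param data An `mr_harmonized` object.
#' @param estimates Estimate tibble from [mr_all()] or friends.
#' @return A ggplot object.
#' @export
scatter_plot <- function(data, estimates) {
  d <- data$data
  flip <- sign(d$beta_exp); flip[flip == 0] <- 1
  pts <- tibble::tibble(x = d$beta_exp * flip, y = d$beta_out * flip,
                        se_x = d$se_exp, se_y = d$se_out)
  lines <- estimates[estimates$method != "egger_intercept", , drop = FALSE]
  intc <- estimates$beta[estimates$method == "egger_intercept"]
  lines$intercept <- ifelse(lines$method == "egger_slope",
                            if (length(intc)) intc else 0, 0)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y - .data$se_y,
                                        ymax = .data$y + .data$se_y),
                           colour = "grey70", width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$x - .data$se_x,
                                         xmax = .data$x + .data$se_x),
                            colour = "grey70", height = 0) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$beta,
                                      intercept = .data$intercept,
                                      colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = "Method") +
    ggplot2::theme_minimal()
}
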