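#' @title Plots for MR results
#' @description
#' ggplot2 figures for the standard MR displays: the per-variant scatter
#' of outcome betas against exposure betas with fitted causal slopes, the
#' forest plot of per-variant Wald ratios, the funnel plot used to judge
#' directional pleiotropy, and the fractional-polynomial dose-response
#' curve.
#' @name plots
NULL

#' Scatter plot of variant-outcome vs variant-exposure betas
#'
#' One point per instrument with +/- 1 SE error bars; causal-estimate
#' lines are drawn through the origin (IVW, medians) or with their fitted
#' intercept (MR-Egger slope rows paired with an `egger_intercept` row).
#'
#' @param hset an `mr_harmonized` tibble.
#' @param estimates optional `mr_estimate` rows to draw as lines.
#' @return a ggplot object.
#' @export
plot_mr_scatter <- function(hset, estimates = NULL) {
  d <- tibble::as_tibble(hset)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$gamma, y = .data$Gamma)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$Gamma - .data$se_Gamma,
                                        ymax = .data$Gamma + .data$se_Gamma),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$gamma - .data$se_gamma,
                                         xmax = .data$gamma + .data$se_gamma),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "variant-exposure beta (SD/allele)",
                  y = "variant-outcome beta (SD/allele)")
  if (!is.null(estimates)) {
    est <- tidy(estimates)
    icpt <- est$beta[est$method == "egger_intercept"]
    lines <- est[!(est$method %in% "egger_intercept"), ]
    lines$intercept <- ifelse(lines$method == "egger_slope",
                              icpt[1] %||% 0, 0)
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$beta, intercept = .data$intercept,
                   colour = .data$method)) +
      ggplot2::labs(colour = "method")
  }
  p
}

#' Forest plot of per-variant Wald ratios
#'
#' @param hset an `mr_harmonized` tibble.
#' @param estimate optional pooled `mr_estimate` drawn as a reference
#'   line.
#' @return a ggplot object.
#' @export
plot_mr_forest <- function(hset, estimate = NULL) {
  d <- wald_ratios(hset)
  d$snp <- factor(d$snp, levels = d$snp[order(d$ratio)])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio, y = .data$snp)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0, linewidth = 0.3) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Wald ratio (SD outcome / SD exposure)", y = NULL)
  if (!is.null(estimate)) {
    p <- p + ggplot2::geom_vline(xintercept = tidy(estimate)$beta[1],
                                 linetype = 2, colour = "firebrick")
  }
  p
}

#' Funnel plot of Wald ratios against precision
#'
#' @param asym an `mr_asymmetry` object from [egger_asymmetry_test()], or
#'   an `mr_harmonized` tibble.
#' @param estimate optional pooled `mr_estimate` drawn as a vertical
#'   reference.
#' @return a ggplot object.
#' @export
plot_mr_funnel <- function(asym, estimate = NULL) {
  if (inherits(asym, "mr_harmonized")) asym <- egger_asymmetry_test(asym)
  d <- tidy(asym)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio,
                                       y = .data$precision)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "Wald ratio", y = "precision (1/SE)")
  if (!is.null(estimate)) {
    p <- p + ggplot2::geom_vline(xintercept = tidy(estimate)$beta[1],
                                 linetype = 2, colour = "firebrick")
  }
  p
}

#' Dose-response plot for a fractional-polynomial fit
#'
#' @param fit an `fp2_fit`.
#' @param points overlay the observations? Default `TRUE`.
#' @return a ggplot object.
#' @export
plot_fp_curve <- function(fit, points = TRUE) {
  curve <- predict(fit)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$fitted))
  if (points) {
    obs <- tibble::tibble(x = fit$x, y = fit$y)
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 alpha = 0.2, size = 0.6)
  }
  p + ggplot2::geom_line(colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = fit$depot,
                  y = paste0(fit$outcome, " (fitted)"))
}

#' @export
autoplot.mr_harmonized <- function(object, ...) plot_mr_scatter(object, ...)

#' @export
autoplot.mr_asymmetry <- function(object, ...) plot_mr_funnel(object, ...)

#' @export
autoplot.fp2_fit <- function(object, ...) plot_fp_curve(object, ...)

#' @export
autoplot.mr_heterogeneity <- function(object, ...) {
  d <- tidy(object)
  d$snp <- factor(d$snp, levels = d$snp[order(d$q)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$snp,
                                  colour = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$flag_threshold, linetype = 2) +
    ggplot2::labs(x = "Q contribution", y = NULL, colour = "flagged")
}
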