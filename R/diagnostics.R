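#' @title Heterogeneity and pleiotropy diagnostics
#' @description
#' Stage-one sensitivity analysis for summary-data MR: Cochran's Q across
#' the per-variant Wald ratios, I-squared with a test-based confidence
#' interval, funnel-plot asymmetry via the MR-Egger intercept, and
#' single-pass removal of heterogeneous variants followed by re-estimation.
#' @name diagnostics
NULL

#' Cochran's Q heterogeneity test across instruments
#'
#' Per-variant contribution `Q_j = w_j (b_j - b_ref)^2` with
#' `w_j = gamma_j^2 / se_Gamma_j^2` and `b_j` the Wald ratio; `Q` is their
#' sum, referred to a chi-squared distribution with `k - 1` degrees of
#' freedom. `I^2 = max(0, (Q - df)/Q) * 100` quantifies the share of
#' between-instrument variation, with a test-based (log-H) 95% CI.
#' Variants with `Q_j` above `flag_threshold` are flagged; the default
#' 3.84 is the chi-squared (1 df) 95th percentile.
#'
#' @param hset an `mr_harmonized` tibble with at least 2 variants.
#' @param reference_beta reference causal effect; defaults to the
#'   fixed-effect IVW estimate on the same set.
#' @param flag_threshold per-variant flagging threshold (default
#'   `qchisq(0.95, 1)` ~ 3.84).
#' @return an `mr_heterogeneity` object. `glance()` gives one row with
#'   `Q`, `df`, `p_het`, `i2`, `i2_ci_low`, `i2_ci_high`, `n_flagged`;
#'   `tidy()` gives the per-variant table (`snp`, `ratio`, `se`, `weight`,
#'   `q`, `flagged`).
#' @export
cochran_q <- function(hset, reference_beta = NULL,
                      flag_threshold = qchisq(0.95, 1)) {
  k <- nrow(hset)
  if (k < 2) stop("heterogeneity assessment needs at least 2 instruments",
                  call. = FALSE)
  if (is.null(reference_beta)) {
    reference_beta <- ivw_core(hset$gamma, hset$Gamma, hset$se_Gamma)$beta
  }
  ratio <- hset$Gamma / hset$gamma
  w <- hset$gamma^2 / hset$se_Gamma^2
  qj <- w * (ratio - reference_beta)^2
  Q <- sum(qj)
  df <- k - 1L
  i2 <- max(0, (Q - df) / Q) * 100
  ci <- i2_confidence_interval(Q, df)
  out <- list(
    Q = Q, df = df, p_het = pchisq(Q, df, lower.tail = FALSE),
    i2 = i2, i2_ci_low = ci[1], i2_ci_high = ci[2],
    reference_beta = reference_beta, flag_threshold = flag_threshold,
    per_snp = tibble::tibble(snp = hset$snp, ratio = ratio,
                             se = hset$se_Gamma / abs(hset$gamma),
                             weight = w, q = qj,
                             flagged = qj > flag_threshold))
  class(out) <- "mr_heterogeneity"
  out
}

#' @export
tidy.mr_heterogeneity <- function(x, ...) x$per_snp

#' @export
glance.mr_heterogeneity <- function(x, ...) {
  tibble::tibble(Q = x$Q, df = x$df, p_het = x$p_het, i2 = x$i2,
                 i2_ci_low = x$i2_ci_low, i2_ci_high = x$i2_ci_high,
                 n_flagged = sum(x$per_snp$flagged))
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.2f on %d df (p = %.3g); I2 = %.1f%% (95%% CI %.1f, %.1f)\n",
              x$Q, x$df, x$p_het, x$i2, x$i2_ci_low, x$i2_ci_high))
  cat(sprintf("%d variant(s) with Q contribution > %.2f\n",
              sum(x$per_snp$flagged), x$flag_threshold))
  invisible(x)
}

#' Test-based confidence interval for I-squared
#'
#' Log-H method: with `H = sqrt(Q/df)`, the standard error of `ln H` is
#' `0.5 * (ln Q - ln df) / (sqrt(2 Q) - sqrt(2 df - 1))` when `Q > df`,
#' and `sqrt(1/(2 (df - 1)) * (1 - 1/(3 (df - 1)^2)))` otherwise; the
#' normal interval for `ln H` is back-transformed through
#' `I^2 = 100 (H^2 - 1)/H^2` and truncated at 0.
#'
#' @param Q Cochran's Q statistic (nonnegative).
#' @param df degrees of freedom, `k - 1 >= 1`.
#' @param level confidence level (default 0.95).
#' @return length-2 vector `(low, high)` in percent.
#' @export
i2_confidence_interval <- function(Q, df, level = 0.95) {
  if (df < 1) stop("df must be at least 1", call. = FALSE)
  if (Q < 0) stop("Q must be nonnegative", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  if (Q > df) {
    se_lnH <- 0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * df - 1))
  } else if (df > 1) {
    se_lnH <- sqrt(1 / (2 * (df - 1)) * (1 - 1 / (3 * (df - 1)^2)))
  } else {
    return(c(0, 0))   # df = 1 with Q <= df: no heterogeneity information
  }
  lnH <- 0.5 * log(max(Q, .Machine$double.xmin) / df)
  H_bounds <- pmax(1, exp(lnH + c(-1, 1) * z * se_lnH))
  i2 <- 100 * (H_bounds^2 - 1) / H_bounds^2
  unname(i2)
}

#' Funnel-plot asymmetry (Egger's test for summary-data MR)
#'
#' Funnel coordinates pair each variant's Wald ratio with its precision
#' (`1/se`); directional pleiotropy shows as asymmetry about the pooled
#' estimate. The test is the MR-Egger intercept on the positively oriented
#' data: intercept, analytic SE, and two-sided normal p-value.
#'
#' @param hset an `mr_harmonized` tibble with at least 3 variants.
#' @return an `mr_asymmetry` object; `tidy()` gives the funnel table
#'   (`snp`, `ratio`, `se`, `precision`), `glance()` the intercept, SE and
#'   p-value.
#' @export
egger_asymmetry_test <- function(hset) {
  if (nrow(hset) < 3) stop("asymmetry test needs at least 3 instruments",
                           call. = FALSE)
  h <- orient_positive(hset)
  fit <- egger_core(h$gamma, h$Gamma, h$se_Gamma)
  ratio <- hset$Gamma / hset$gamma
  se <- hset$se_Gamma / abs(hset$gamma)
  out <- list(egger_intercept = fit$intercept,
              intercept_se = fit$se_intercept,
              p_asym = 2 * pnorm(-abs(fit$intercept / fit$se_intercept)),
              funnel = tibble::tibble(snp = hset$snp, ratio = ratio, se = se,
                                      precision = 1 / se))
  class(out) <- "mr_asymmetry"
  out
}

#' @export
tidy.mr_asymmetry <- function(x, ...) x$funnel

#' @export
glance.mr_asymmetry <- function(x, ...) {
  tibble::tibble(egger_intercept = x$egger_intercept,
                 intercept_se = x$intercept_se, p_asym = x$p_asym)
}

#' @export
print.mr_asymmetry <- function(x, ...) {
  cat(sprintf("Egger asymmetry test: intercept = %.4f (SE %.4f), p = %.3g\n",
              x$egger_intercept, x$intercept_se, x$p_asym))
  invisible(x)
}

#' Remove heterogeneous variants and re-estimate
#'
#' Single pass: Cochran's Q contributions are computed against the
#' full-set fixed-effect IVW estimate, variants with a contribution above
#' `flag_threshold` are dropped, and IVW is re-run on the remainder.
#' The pass is deliberately not iterated: repeating it on the reduced set
#' may flag further variants, and iterating turns a diagnostic into an
#' outlier hunt.
#'
#' @param hset an `mr_harmonized` tibble with at least 2 variants.
#' @param flag_threshold per-variant Q threshold (default
#'   `qchisq(0.95, 1)` ~ 3.84).
#' @param variance_model variance model for the re-estimated IVW.
#' @return a list with `hset` (the reduced set), `estimate` (the new IVW
#'   `mr_estimate`), `removed` (tibble of dropped variants with their Q
#'   contributions), and `heterogeneity` (the full-set
#'   `mr_heterogeneity`).
#' @export
remove_heterogeneous_and_reestimate <- function(hset,
                                                flag_threshold = qchisq(0.95, 1),
                                                variance_model = "fixed") {
  het <- cochran_q(hset, flag_threshold = flag_threshold)
  flagged <- het$per_snp$flagged
  if (all(flagged)) stop("all variants flagged as heterogeneous",
                         call. = FALSE)
  reduced <- slice_hset(hset, !flagged)
  attr(reduced, "dropped") <- dplyr::bind_rows(
    dropped_snps(hset),
    tibble::tibble(snp = hset$snp[flagged],
                   reason = sprintf("Q contribution > %.3g", flag_threshold)))
  est <- mr_ivw(reduced, variance_model = variance_model)
  list(hset = reduced, estimate = est,
       removed = het$per_snp[flagged, ], heterogeneity = het)
}
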