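#' @title Causal-effect estimators for summary-data MR
#' @description
#' All estimators consume an `mr_harmonized` tibble (see [harmonize()]) and
#' return an `mr_estimate`: a one-row (two-row for MR-Egger) tibble with
#' columns `method`, `exposure`, `direction`, `k`, `beta`, `se`, `ci_low`,
#' `ci_high`, `pvalue`, in SD units of the outcome per SD of the exposure.
#' @name estimators
NULL

Z975 <- qnorm(0.975)

new_mr_estimate <- function(method, exposure, k, beta, se, ci_low, ci_high,
                            pvalue, direction = "forward") {
  out <- tibble::tibble(method = method, exposure = exposure,
                        direction = direction, k = as.integer(k),
                        beta = beta, se = se, ci_low = ci_low,
                        ci_high = ci_high, pvalue = pvalue)
  class(out) <- c("mr_estimate", class(out))
  out
}

#' @export
tidy.mr_estimate <- function(x, ...) {
  class(x) <- setdiff(class(x), "mr_estimate")
  x
}

#' @export
glance.mr_estimate <- function(x, ...) {
  tibble::tibble(methods = paste(x$method, collapse = ", "),
                 k = max(x$k), exposure = x$exposure[1])
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat("<MR estimate>\n")
  print(tidy(x), ...)
  invisible(x)
}

exposure_label <- function(hset, which = 1) {
  nm <- if (which == 1) attr(hset, "exposure_name") else attr(hset, "exposure2_name")
  if (is.null(nm) || is.na(nm)) paste0("exposure", if (which == 2) "2" else "") else nm
}

normal_ci_p <- function(beta, se) {
  list(ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
       pvalue = 2 * pnorm(-abs(beta / se)))
}

#' Wald ratio for a single variant
#'
#' The per-variant causal estimate: the variant-outcome beta divided by the
#' variant-exposure beta, with first-order delta-method standard error
#' `se_Gamma / |gamma|` (the exposure-beta sampling error is ignored, as is
#' conventional for strong instruments).
#'
#' @param gamma,se_gamma variant-exposure beta and SE.
#' @param Gamma,se_Gamma variant-outcome beta and SE.
#' @param exposure label for the exposure trait.
#' @return an `mr_estimate` tibble (one row, method `"wald"`).
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma,
                       exposure = "exposure") {
  if (gamma == 0) stop("undefined Wald ratio: gamma is zero", call. = FALSE)
  beta <- Gamma / gamma
  se <- se_Gamma / abs(gamma)
  cp <- normal_ci_p(beta, se)
  new_mr_estimate("wald", exposure, 1L, beta, se, cp$ci_low, cp$ci_high,
                  cp$pvalue)
}

#' Per-variant Wald ratios of a harmonized set
#'
#' The forest-plot table: one row per variant with its ratio estimate,
#' delta-method SE, normal 95% CI, and IVW weight.
#'
#' @param hset an `mr_harmonized` tibble.
#' @return a tibble with columns `snp`, `ratio`, `se`, `ci_low`, `ci_high`,
#'   `weight` (`gamma^2 / se_Gamma^2`) and `precision` (`1/se`).
#' @export
wald_ratios <- function(hset) {
  ratio <- hset$Gamma / hset$gamma
  se <- hset$se_Gamma / abs(hset$gamma)
  tibble::tibble(snp = hset$snp, ratio = ratio, se = se,
                 ci_low = ratio - Z975 * se, ci_high = ratio + Z975 * se,
                 weight = hset$gamma^2 / hset$se_Gamma^2,
                 precision = 1 / se)
}

# core IVW computation on vectors
ivw_core <- function(g, G, sG, variance_model = "fixed") {
  w <- 1 / sG^2
  denom <- sum(w * g^2)
  beta <- sum(w * g * G) / denom
  se <- sqrt(1 / denom)
  k <- length(g)
  Q <- sum((G - beta * g)^2 / sG^2)
  if (variance_model == "multiplicative_random" && k > 1) {
    se <- se * max(1, sqrt(Q / (k - 1)))
  }
  list(beta = beta, se = se, Q = Q, k = k)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Precision-weighted combination of the per-variant Wald ratios,
#' equivalently the weighted least-squares slope of the outcome betas on
#' the exposure betas through the origin with weights `1/se_Gamma^2`.
#' The fixed-effect SE is `(sum gamma^2/se_Gamma^2)^(-1/2)`; the
#' multiplicative random-effects model inflates it by
#' `max(1, sqrt(Q/(k-1)))`, appropriate when the instruments are
#' heterogeneous.
#'
#' @param hset an `mr_harmonized` tibble.
#' @param variance_model `"fixed"` (default) or `"multiplicative_random"`.
#' @param direction `"forward"` or `"reverse"`, a label only.
#' @return an `mr_estimate` tibble (method `"ivw"`).
#' @export
mr_ivw <- function(hset, variance_model = c("fixed", "multiplicative_random"),
                   direction = "forward") {
  variance_model <- match.arg(variance_model)
  if (nrow(hset) < 1) stop("empty instrument set", call. = FALSE)
  fit <- ivw_core(hset$gamma, hset$Gamma, hset$se_Gamma, variance_model)
  cp <- normal_ci_p(fit$beta, fit$se)
  new_mr_estimate("ivw", exposure_label(hset), fit$k, fit$beta, fit$se,
                  cp$ci_low, cp$ci_high, cp$pvalue, direction = direction)
}

#' Reverse-direction IVW estimate
#'
#' Identical computation to [mr_ivw()] on a harmonized set built with the
#' roles swapped (here, adiponectin instruments against a girth outcome);
#' only the labelling differs.
#'
#' @inheritParams mr_ivw
#' @return an `mr_estimate` tibble (method `"ivw"`, direction `"reverse"`).
#' @export
reverse_mr <- function(hset, variance_model = c("fixed",
                                                "multiplicative_random")) {
  mr_ivw(hset, variance_model = match.arg(variance_model),
         direction = "reverse")
}

#' Multivariable IVW estimate for two correlated exposures
#'
#' Origin-constrained weighted least squares of the outcome betas on both
#' exposures' betas with weights `1/se_Gamma^2`, giving mutually adjusted
#' causal effects (each exposure's effect holding the other fixed).
#' Per-coefficient SEs come from the weighted normal-equations covariance
#' `(X' W X)^(-1)`.
#'
#' @param hset an `mr_harmonized` tibble with `gamma2` present.
#' @return an `mr_estimate` tibble with two rows (method `"mv_ivw"`), one
#'   per exposure.
#' @export
mr_mv_ivw <- function(hset) {
  if (!("gamma2" %in% names(hset))) {
    stop("multivariable IVW needs a second exposure (gamma2)", call. = FALSE)
  }
  if (nrow(hset) < 3) stop("multivariable IVW needs at least 3 instruments",
                           call. = FALSE)
  if (all(hset$gamma2 == 0)) {
    # degenerate second exposure: model reduces to the univariable IVW
    warn("second exposure carries no signal; returning the univariable IVW")
    uni <- mr_ivw(hset)
    uni$method <- "mv_ivw"
    return(uni)
  }
  X <- cbind(hset$gamma, hset$gamma2)
  w <- 1 / hset$se_Gamma^2
  XtWX <- crossprod(X, w * X)
  if (abs(det(XtWX)) < .Machine$double.eps * max(abs(XtWX))^2) {
    stop("rank-deficient design: the two exposures' betas are collinear",
         call. = FALSE)
  }
  coefs <- drop(solve(XtWX, crossprod(X, w * hset$Gamma)))
  se <- unname(sqrt(diag(solve(XtWX))))
  out <- lapply(1:2, function(i) {
    cp <- normal_ci_p(coefs[i], se[i])
    new_mr_estimate("mv_ivw", exposure_label(hset, i), nrow(hset),
                    coefs[i], se[i], cp$ci_low, cp$ci_high, cp$pvalue)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("mr_estimate", class(res))
  res
}

# orient so every exposure beta is positive (Egger convention)
orient_positive <- function(hset) {
  s <- sign(hset$gamma)
  s[s == 0] <- 1
  hset$gamma <- hset$gamma * s
  hset$Gamma <- hset$Gamma * s
  if ("gamma2" %in% names(hset)) hset$gamma2 <- hset$gamma2 * s
  hset
}

egger_core <- function(g, G, sG) {
  w <- 1 / sG^2
  X <- cbind(1, g)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * G))
  resid <- G - X %*% coefs
  k <- length(g)
  sigma2 <- sum(w * resid^2) / (k - 2)
  se <- unname(sqrt(diag(solve(XtWX)) * sigma2))
  list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
       se_intercept = se[1], se_slope = se[2], sigma2 = sigma2)
}

boot_indices <- function(k, n_boot) {
  matrix(sample.int(k, k * n_boot, replace = TRUE), nrow = n_boot)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome betas on the exposure betas with
#' an unconstrained intercept (weights `1/se_Gamma^2`), after orienting
#' every variant to a positive exposure beta. Under the InSIDE assumption
#' the slope is a consistent causal estimate even when all instruments are
#' pleiotropic, and the intercept estimates the average directional
#' pleiotropic effect. Confidence intervals are percentile-bootstrap over
#' variants (resampled with replacement) when `n_boot > 0`, otherwise
#' analytic; analytic SEs are always reported and p-values are two-sided
#' normal from `beta/se`.
#'
#' @param hset an `mr_harmonized` tibble with at least 3 variants.
#' @param n_boot bootstrap replicates (0 for analytic CIs only; otherwise
#'   at least 100). Default 1000.
#' @param seed optional seed for the bootstrap resampling.
#' @return an `mr_estimate` tibble with rows `egger_slope` and
#'   `egger_intercept`.
#' @export
mr_egger <- function(hset, n_boot = 1000, seed = NULL) {
  if (nrow(hset) < 3) stop("MR-Egger needs at least 3 instruments",
                           call. = FALSE)
  if (n_boot > 0 && n_boot < 100) stop("n_boot must be 0 or >= 100",
                                       call. = FALSE)
  h <- orient_positive(hset)
  fit <- egger_core(h$gamma, h$Gamma, h$se_Gamma)
  cp_s <- normal_ci_p(fit$slope, fit$se_slope)
  cp_i <- normal_ci_p(fit$intercept, fit$se_intercept)
  ci <- list(slope = c(cp_s$ci_low, cp_s$ci_high),
             intercept = c(cp_i$ci_low, cp_i$ci_high))
  if (n_boot > 0) {
    k <- nrow(h)
    draws <- with_seed(seed, {
      idx <- boot_indices(k, n_boot)
      t(apply(idx, 1, function(i) {
        b <- egger_core(h$gamma[i], h$Gamma[i], h$se_Gamma[i])
        c(b$slope, b$intercept)
      }))
    })
    ci <- list(slope = unname(quantile(draws[, 1], c(0.025, 0.975))),
               intercept = unname(quantile(draws[, 2], c(0.025, 0.975))))
  }
  res <- dplyr::bind_rows(
    new_mr_estimate("egger_slope", exposure_label(hset), nrow(h),
                    fit$slope, fit$se_slope, ci$slope[1], ci$slope[2],
                    cp_s$pvalue),
    new_mr_estimate("egger_intercept", exposure_label(hset), nrow(h),
                    fit$intercept, fit$se_intercept, ci$intercept[1],
                    ci$intercept[2], cp_i$pvalue))
  class(res) <- c("mr_estimate", class(res))
  res
}

# interpolated weighted median of `b` with weights `w`
weighted_median_core <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  approx(s, b, xout = 0.5, ties = "ordered")$y
}

median_weights <- function(hset, penalized, penalty_scale) {
  b <- hset$Gamma / hset$gamma
  w <- hset$gamma^2 / hset$se_Gamma^2
  if (penalized) {
    b0 <- weighted_median_core(b, w)
    qj <- pchisq(w * (b - b0)^2, df = 1, lower.tail = FALSE)
    w <- w * pmin(1, penalty_scale * qj)
    if (all(w == 0)) stop("all weights zero after penalization",
                          call. = FALSE)
  }
  list(b = b, w = w)
}

#' (Penalized) weighted median estimate
#'
#' The causal estimate at the 50% point of the weight-ordered per-variant
#' Wald ratios, with inverse-variance weights `gamma^2/se_Gamma^2` and
#' linear interpolation of the cumulative-weight midpoints. Consistent when
#' valid instruments carry a majority of the weight. The penalized variant
#' downweights heterogeneous variants: each weight is multiplied by
#' `min(1, penalty_scale * q_j)` where `q_j` is the upper-tail chi-squared
#' (1 df) probability of the variant's heterogeneity contribution relative
#' to the unpenalized weighted-median estimate. Confidence intervals are
#' percentile-bootstrap over variants; the SE is the bootstrap SD and the
#' p-value the matching two-sided normal approximation.
#'
#' @param hset an `mr_harmonized` tibble with at least 3 variants.
#' @param penalized downweight heterogeneous variants? Default `FALSE`.
#' @param penalty_scale weight multiplier constant (default 20).
#' @param n_boot bootstrap replicates, at least 100 (default 1000).
#' @param seed optional seed for the bootstrap resampling.
#' @return an `mr_estimate` tibble (method `"weighted_median"` or
#'   `"penalized_weighted_median"`).
#' @export
mr_weighted_median <- function(hset, penalized = FALSE, penalty_scale = 20,
                               n_boot = 1000, seed = NULL) {
  if (nrow(hset) < 3) stop("weighted median needs at least 3 instruments",
                           call. = FALSE)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  bw <- median_weights(hset, penalized, penalty_scale)
  est <- weighted_median_core(bw$b, bw$w)
  k <- nrow(hset)
  draws <- with_seed(seed, {
    idx <- boot_indices(k, n_boot)
    apply(idx, 1, function(i) {
      bwi <- median_weights(hset[i, ], penalized, penalty_scale)
      weighted_median_core(bwi$b, bwi$w)
    })
  })
  se <- sd(draws)
  ci <- unname(quantile(draws, c(0.025, 0.975)))
  pvalue <- 2 * pnorm(-abs(est / se))
  new_mr_estimate(if (penalized) "penalized_weighted_median" else "weighted_median",
                  exposure_label(hset), k, est, se, ci[1], ci[2], pvalue)
}
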