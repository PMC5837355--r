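#' @title Fractional-polynomial dose-response modelling
#' @description
#' The cohort arm of the analysis: standardized linear regressions of
#' log-adiponectin on each fat depot, and two-degree fractional-polynomial
#' (FP2) models to detect nonlinear dose-response, compared with the linear
#' model by likelihood-ratio test with Bonferroni correction across the
#' depot-by-sex models.
#' @name fractional_polynomials
NULL

FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

# one FP term: x^p with the convention x^0 = ln x
fp_term <- function(x, p) if (p == 0) log(x) else x^p

# FP2 basis for a power pair; repeated powers (p, p) -> (x^p, x^p ln x)
fp_basis <- function(x, p1, p2) {
  t1 <- fp_term(x, p1)
  t2 <- if (p1 == p2) t1 * log(x) else fp_term(x, p2)
  cbind(t1, t2)
}

gaussian_deviance <- function(rss, n) n * (log(2 * pi * rss / n) + 1)

ols_deviance <- function(X, y) {
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(deviance = gaussian_deviance(rss, length(y)), fit = fit, rss = rss)
}

covariate_matrix <- function(data, covariates) {
  if (length(covariates) == 0) return(NULL)
  mm <- model.matrix(~ ., data = as.data.frame(data[covariates]))
  mm[, -1, drop = FALSE]
}

#' Fit the best two-degree fractional polynomial for a depot
#'
#' Evaluates all 36 FP2 power pairs from `{-2, -1, -0.5, 0, 0.5, 1, 2, 3}`
#' (with `x^0 = ln x` and repeated powers `(p, p)` giving
#' `(x^p, x^p ln x)`), fitting each by OLS of the outcome on the two
#' transformed depot terms plus covariates. The minimum-deviance pair is
#' retained and compared with the corresponding linear model by
#' likelihood-ratio test on 3 degrees of freedom (two power choices plus
#' one coefficient). Depot values must be positive; if any value is
#' nonpositive, half the smallest positive value is added to all before
#' transformation.
#'
#' @param data cohort table (complete cases).
#' @param depot name of the depot column (raw positive scale).
#' @param outcome name of the outcome column (standardized
#'   log-adiponectin). Default `"log_adiponectin"`.
#' @param covariates character vector of adjustment columns (categorical
#'   columns are expanded to indicators).
#' @return an `fp2_fit` object: `powers`, `deviance`, `coefficients`,
#'   `lr_stat`, `lr_df`, `lr_p` (vs. linear), `linear_deviance`, and the
#'   full 36-row `grid`. `glance()` returns the one-row summary, `tidy()`
#'   the coefficient table.
#' @export
fp2_fit <- function(data, depot, outcome = "log_adiponectin",
                    covariates = character()) {
  stopifnot(depot %in% names(data), outcome %in% names(data))
  data <- data[complete.cases(data[c(depot, outcome, covariates)]), ]
  x <- as.numeric(data[[depot]])
  y <- as.numeric(data[[outcome]])
  shift <- 0
  if (any(x <= 0)) {
    pos <- x[x > 0]
    if (length(pos) == 0) stop("depot has no positive values", call. = FALSE)
    shift <- min(pos) / 2
    x <- x + shift
    if (any(x <= 0)) stop("nonpositive depot values remain after shift",
                          call. = FALSE)
  }
  C <- covariate_matrix(data, covariates)
  n <- length(y)
  if (n <= 3 + ifelse(is.null(C), 0, ncol(C))) {
    stop("too few observations for the FP2 design", call. = FALSE)
  }

  lin <- ols_deviance(cbind(`(Intercept)` = 1, depot = scale(x)[, 1], C), y)

  pairs <- expand.grid(p1 = FP_POWERS, p2 = FP_POWERS)
  pairs <- pairs[pairs$p1 <= pairs$p2, ]
  scan <- purrr::pmap(pairs, function(p1, p2) {
    B <- scale(fp_basis(x, p1, p2))
    ols_deviance(cbind(`(Intercept)` = 1, B, C), y)$deviance
  })
  grid <- tibble::tibble(p1 = pairs$p1, p2 = pairs$p2,
                         deviance = unlist(scan))
  best <- which.min(grid$deviance)
  p1 <- grid$p1[best]
  p2 <- grid$p2[best]
  B <- scale(fp_basis(x, p1, p2))
  X <- cbind(`(Intercept)` = 1, fp1 = B[, 1], fp2 = B[, 2], C)
  fit <- ols_deviance(X, y)
  lr_stat <- max(0, lin$deviance - grid$deviance[best])
  out <- list(
    powers = c(p1, p2), deviance = grid$deviance[best],
    coefficients = fit$fit$coefficients,
    lr_stat = lr_stat, lr_df = 3,
    lr_p = pchisq(lr_stat, df = 3, lower.tail = FALSE),
    linear_deviance = lin$deviance, grid = grid,
    depot = depot, outcome = outcome, n = n, shift = shift,
    basis_center = attr(B, "scaled:center"),
    basis_scale = attr(B, "scaled:scale"),
    x = x, y = y)
  class(out) <- "fp2_fit"
  out
}

#' Predict the depot partial effect from an FP2 fit
#'
#' Fitted curve on the depot scale with covariates held at their reference
#' (zero) level; used for dose-response plots.
#'
#' @param object an `fp2_fit`.
#' @param newx depot values at which to evaluate (default: 200 points over
#'   the observed range).
#' @param ... unused.
#' @return a tibble with columns `x`, `fitted`.
#' @export
predict.fp2_fit <- function(object, newx = NULL, ...) {
  if (is.null(newx)) {
    newx <- seq(min(object$x), max(object$x), length.out = 200)
  }
  B <- fp_basis(newx, object$powers[1], object$powers[2])
  B <- sweep(sweep(B, 2, object$basis_center), 2, object$basis_scale, "/")
  co <- object$coefficients
  tibble::tibble(x = newx,
                 fitted = co[["(Intercept)"]] +
                   B[, 1] * co[["fp1"]] + B[, 2] * co[["fp2"]])
}

#' @export
glance.fp2_fit <- function(x, ...) {
  tibble::tibble(p1 = x$powers[1], p2 = x$powers[2], deviance = x$deviance,
                 linear_deviance = x$linear_deviance, lr_stat = x$lr_stat,
                 lr_df = x$lr_df, lr_p = x$lr_p, n = x$n)
}

#' @export
tidy.fp2_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
print.fp2_fit <- function(x, ...) {
  cat(sprintf("FP2 fit for %s: powers (%g, %g), deviance %.2f\n",
              x$depot, x$powers[1], x$powers[2], x$deviance))
  cat(sprintf("LR vs linear: %.2f on %d df, p = %.3g\n",
              x$lr_stat, x$lr_df, x$lr_p))
  invisible(x)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise level, in (0, 1).
#' @param m number of tests, at least 1.
#' @return `alpha / m` (e.g. 0.05 over 8 depot-by-sex models gives
#'   0.00625).
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (m < 1 || m != round(m)) stop("m must be a positive integer",
                                   call. = FALSE)
  alpha / m
}

std_within <- function(x) (x - mean(x)) / sd(x)

#' Standardized linear regression of adiponectin on a fat depot
#'
#' OLS of the outcome (assumed already in SD units of log-adiponectin) on
#' the standardized depot, either unadjusted or adjusted for covariates
#' and the other depots. When a `sex` column is present the model is
#' fitted separately by sex, standardizing the depot columns within sex.
#'
#' @param data cohort table (complete cases).
#' @param depot name of the depot column of interest.
#' @param adjusted include `covariates` and `other_depots`? Default
#'   `FALSE`.
#' @param outcome outcome column name (default `"log_adiponectin"`).
#' @param covariates adjustment columns (used when `adjusted = TRUE`).
#' @param other_depots other depot columns, standardized and included when
#'   `adjusted = TRUE`.
#' @return a tibble of coefficient rows: `sex` (if stratified), `term`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `pvalue`. Estimates are SD
#'   outcome per SD depot.
#' @export
standardized_regression <- function(data, depot, adjusted = FALSE,
                                    outcome = "log_adiponectin",
                                    covariates = character(),
                                    other_depots = character()) {
  fit_one <- function(d) {
    cols <- c(depot, if (adjusted) other_depots)
    d[cols] <- lapply(d[cols], std_within)
    rhs <- c(depot, if (adjusted) c(other_depots, covariates))
    f <- stats::reformulate(rhs, response = outcome)
    fit <- lm(f, data = d)
    sm <- summary(fit)$coefficients
    est <- unname(sm[, 1])
    se <- unname(sm[, 2])
    tibble::tibble(term = rownames(sm), estimate = est, se = se,
                   ci_low = est - Z975 * se, ci_high = est + Z975 * se,
                   pvalue = 2 * pnorm(-abs(est / se)))
  }
  data <- data[complete.cases(data[c(depot, outcome,
                                     if (adjusted) c(covariates, other_depots))]), ]
  if ("sex" %in% names(data)) {
    dplyr::bind_rows(lapply(split(data, data$sex), fit_one), .id = "sex")
  } else {
    fit_one(data)
  }
}

#' Scan all depot-by-sex FP2 models for nonlinearity
#'
#' Fits [fp2_fit()] for each depot within each sex and reports the
#' likelihood-ratio p-values against the Bonferroni-corrected threshold
#' for the family of models.
#'
#' @param data cohort table with a `sex` column.
#' @param depots character vector of depot columns.
#' @param outcome,covariates passed to [fp2_fit()].
#' @param alpha family-wise level (default 0.05).
#' @return a tibble with one row per sex-by-depot model: `sex`, `depot`,
#'   `p1`, `p2`, `lr_stat`, `lr_p`, `threshold`, `nonlinear`.
#' @export
fp_nonlinearity_scan <- function(data, depots,
                                 outcome = "log_adiponectin",
                                 covariates = character(), alpha = 0.05) {
  stopifnot("sex" %in% names(data))
  sexes <- unique(data$sex)
  m <- length(depots) * length(sexes)
  thr <- bonferroni_threshold(alpha, m)
  rows <- purrr::map_dfr(sexes, function(s) {
    d <- data[data$sex == s, ]
    purrr::map_dfr(depots, function(dep) {
      f <- fp2_fit(d, dep, outcome = outcome, covariates = covariates)
      tibble::tibble(sex = s, depot = dep, p1 = f$powers[1],
                     p2 = f$powers[2], lr_stat = f$lr_stat, lr_p = f$lr_p)
    })
  })
  rows$threshold <- thr
  rows$nonlinear <- rows$lr_p < thr
  rows
}
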