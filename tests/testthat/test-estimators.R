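test_that("Wald ratio: scaling and delta-method SE", {
  w1 <- tidy(wald_ratio(1, 0.01, 0.5, 0.1))
  expect_equal(w1$beta, 0.5)
  expect_equal(w1$se, 0.1)
  w2 <- tidy(wald_ratio(2, 0.01, 1.0, 0.2))
  expect_equal(w2$beta, 0.5)
  expect_equal(w2$se, 0.1)
  expect_error(wald_ratio(0, 0.01, 0.5, 0.1), "gamma is zero")
})

test_that("first-order ratio SE understates the sampling SD as simulation shows", {
  gamma <- 0.1; se_gamma <- 0.01; Gamma <- 0.05; se_Gamma <- 0.01
  first_order <- se_Gamma / abs(gamma)
  second_order <- sqrt(se_Gamma^2 / gamma^2 +
                         Gamma^2 * se_gamma^2 / gamma^4)
  set.seed(51)
  draws <- (Gamma + rnorm(1e5, 0, se_Gamma)) / (gamma + rnorm(1e5, 0, se_gamma))
  emp <- sd(draws)
  expect_lt(first_order, emp)
  expect_equal(emp, second_order, tolerance = 0.03)
})

test_that("IVW: single-instrument identity and precision addition", {
  h1 <- harmonized_set(gamma = 0.1, se_gamma = 0.01, Gamma = 0.05,
                       se_Gamma = 0.02)
  expect_equal(tidy(mr_ivw(h1))$beta, tidy(wald_ratio(0.1, 0.01, 0.05, 0.02))$beta)
  expect_equal(tidy(mr_ivw(h1))$se, tidy(wald_ratio(0.1, 0.01, 0.05, 0.02))$se)
  h2 <- harmonized_set(gamma = c(0.1, 0.1), se_gamma = c(0.01, 0.01),
                       Gamma = c(0.05, 0.05), se_Gamma = c(0.02, 0.02))
  expect_equal(tidy(mr_ivw(h2))$beta, tidy(mr_ivw(h1))$beta)
  expect_equal(tidy(mr_ivw(h2))$se, tidy(mr_ivw(h1))$se / sqrt(2))
})

test_that("IVW equals the generic origin-constrained WLS oracle", {
  for (seed in 1:5) {
    h <- random_hset(12, seed = seed)
    o <- oracle_wls_origin(h$gamma, h$Gamma, 1 / h$se_Gamma^2)
    est <- tidy(mr_ivw(h))
    expect_equal(est$beta, o$beta, tolerance = 1e-10)
    expect_equal(est$se, o$se, tolerance = 1e-10)
  }
})

test_that("multiplicative random-effects SE never shrinks below fixed", {
  h <- random_hset(15, seed = 3, se_G = 0.02)
  expect_gte(tidy(mr_ivw(h, "multiplicative_random"))$se,
             tidy(mr_ivw(h, "fixed"))$se)
})

test_that("multivariable IVW: reduction, interpolation, WLS oracle", {
  # second exposure carrying no signal: exposure-1 estimate is univariable
  h0 <- random_hset(10, seed = 7)
  h <- harmonized_set(gamma = h0$gamma, se_gamma = h0$se_gamma,
                      Gamma = h0$Gamma, se_Gamma = h0$se_Gamma,
                      gamma2 = rep(0, 10), se_gamma2 = h0$se_gamma)
  expect_warning(mv0 <- mr_mv_ivw(h), "no signal")
  expect_equal(tidy(mv0)$beta[1], tidy(mr_ivw(h0))$beta, tolerance = 1e-12)

  # noise-free bilinear data is interpolated exactly
  set.seed(8)
  g1 <- rnorm(10, 0.1, 0.03); g2 <- rnorm(10, 0.1, 0.03)
  hx <- harmonized_set(gamma = g1, se_gamma = rep(0.01, 10),
                       gamma2 = g2, se_gamma2 = rep(0.01, 10),
                       Gamma = 0.5 * g1 - 0.3 * g2,
                       se_Gamma = rep(0.02, 10))
  expect_equal(tidy(mr_mv_ivw(hx))$beta, c(0.5, -0.3), tolerance = 1e-10)

  # noisy case matches the generic two-regressor WLS oracle
  set.seed(9)
  hy <- harmonized_set(gamma = g1, se_gamma = rep(0.01, 10),
                       gamma2 = g2, se_gamma2 = rep(0.01, 10),
                       Gamma = 0.5 * g1 - 0.3 * g2 + rnorm(10, 0, 0.02),
                       se_Gamma = abs(rnorm(10, 0.02, 0.005)) + 0.001)
  o <- oracle_wls_two(g1, g2, hy$Gamma, 1 / hy$se_Gamma^2)
  expect_equal(tidy(mr_mv_ivw(hy))$beta, o$beta, tolerance = 1e-10)
  expect_equal(tidy(mr_mv_ivw(hy))$se, o$se, tolerance = 1e-10)

  # collinear exposures are refused
  hz <- harmonized_set(gamma = g1, se_gamma = rep(0.01, 10),
                       gamma2 = 2 * g1, se_gamma2 = rep(0.01, 10),
                       Gamma = g1, se_Gamma = rep(0.02, 10))
  expect_error(mr_mv_ivw(hz), "collinear")
})

test_that("MR-Egger: exact line, IVW nesting, bootstrap consistency", {
  set.seed(10)
  g <- abs(rnorm(10, 0.1, 0.03))
  h <- harmonized_set(gamma = g, se_gamma = rep(0.01, 10),
                      Gamma = 0.02 + 0.4 * g, se_Gamma = rep(0.02, 10))
  eg <- tidy(mr_egger(h, n_boot = 0))
  expect_equal(eg$beta[eg$method == "egger_slope"], 0.4, tolerance = 1e-10)
  expect_equal(eg$beta[eg$method == "egger_intercept"], 0.02,
               tolerance = 1e-10)

  # constraining the intercept to zero is exactly the fixed-effect IVW
  hh <- random_hset(20, seed = 12)
  o <- oracle_wls_origin(hh$gamma, hh$Gamma, 1 / hh$se_Gamma^2)
  expect_equal(tidy(mr_ivw(hh))$beta, o$beta, tolerance = 1e-12)

  # bootstrap percentile CI close to the analytic one on homogeneous data
  hb <- random_hset(40, beta = 0.3, seed = 13, se_G = 0.02)
  ega <- tidy(mr_egger(hb, n_boot = 0))
  egb <- tidy(mr_egger(hb, n_boot = 2000, seed = 1))
  width_a <- ega$ci_high - ega$ci_low
  width_b <- egb$ci_high - egb$ci_low
  expect_equal(width_b[1], width_a[1], tolerance = 0.2)
  expect_error(mr_egger(random_hset(2, seed = 1)), "at least 3")
})

test_that("MR-Egger recovers mean directional pleiotropy under InSIDE", {
  # instrument strengths bounded away from zero (so orientation is never
  # ambiguous) and direct effects independent of strength
  set.seed(61)
  res <- sapply(1:500, function(i) {
    k <- 30
    g_true <- runif(k, 0.05, 0.15)
    alpha <- rnorm(k, 0.03, 0.004)
    sG <- rep(0.02, k)
    g <- g_true + rnorm(k, 0, 0.004)
    G <- 0.2 * g_true + alpha + rnorm(k, 0, sG)
    h <- harmonized_set(gamma = g, se_gamma = rep(0.004, k), Gamma = G,
                        se_Gamma = sG)
    est <- tidy(mr_egger(h, n_boot = 0))
    c(slope = est$beta[1], intercept = est$beta[2])
  })
  expect_lt(abs(mean(res["intercept", ]) - 0.03), 0.005)
  expect_lt(abs(mean(res["slope", ]) - 0.2), 0.05)
})

test_that("weighted median: midpoint rule, degenerate cases, quantile oracle", {
  h <- harmonized_set(gamma = c(1, 1, 1), se_gamma = rep(0.01, 3),
                      Gamma = c(0.1, 0.2, 0.9), se_Gamma = rep(0.1, 3))
  expect_equal(tidy(mr_weighted_median(h, n_boot = 100, seed = 1))$beta, 0.2)

  hc <- harmonized_set(gamma = c(0.5, 1, 2, 4), se_gamma = rep(0.01, 4),
                       Gamma = 0.7 * c(0.5, 1, 2, 4),
                       se_Gamma = c(0.1, 0.3, 0.2, 0.4))
  expect_equal(tidy(mr_weighted_median(hc, n_boot = 100, seed = 1))$beta, 0.7)

  set.seed(71)
  for (rep in 1:10) {
    g <- rnorm(7, 0.1, 0.04)
    sG <- abs(rnorm(7, 0.05, 0.02)) + 0.005
    G <- 0.3 * g + rnorm(7, 0, sG)
    h7 <- harmonized_set(gamma = g, se_gamma = rep(0.01, 7), Gamma = G,
                         se_Gamma = sG)
    est <- tidy(mr_weighted_median(h7, n_boot = 100, seed = rep))$beta
    expect_equal(est, oracle_weighted_quantile(G / g, g^2 / sG^2, 0.5),
                 tolerance = 1e-12)
  }
  expect_error(mr_weighted_median(random_hset(2, seed = 1)), "at least 3")
})

test_that("penalization downweights a planted heterogeneous variant", {
  set.seed(81)
  g <- abs(rnorm(15, 0.1, 0.02))
  sG <- rep(0.01, 15)
  G <- 0.3 * g
  G[1] <- 0.3 * g[1] + 0.2   # gross outlier
  h <- harmonized_set(gamma = g, se_gamma = rep(0.005, 15), Gamma = G,
                      se_Gamma = sG)
  plain <- tidy(mr_weighted_median(h, n_boot = 100, seed = 2))$beta
  pen <- tidy(mr_weighted_median(h, penalized = TRUE, n_boot = 100,
                                 seed = 2))$beta
  expect_lt(abs(pen - 0.3), abs(plain - 0.3) + 1e-12)
  expect_lt(abs(pen - 0.3), 0.01)
})

test_that("penalized median resists 30% invalid variants carrying ~49% of weight", {
  # strong instruments, large directional pleiotropy on the invalid block:
  # the median downweights the heterogeneous half of the weight while IVW
  # is dragged far from the truth
  set.seed(202)
  res <- sapply(1:200, function(i) {
    g_true <- c(rep(0.3, 21), rep(0.45, 9))
    alpha <- c(rep(0, 21), rep(0.5, 9))
    sG <- rep(0.003, 30)
    sg <- rep(0.002, 30)
    g <- g_true + rnorm(30, 0, sg)
    G <- -0.27 * g_true + alpha + rnorm(30, 0, sG)
    h <- harmonized_set(gamma = g, se_gamma = sg, Gamma = G, se_Gamma = sG)
    c(ivw = tidy(mr_ivw(h))$beta,
      pwm = tidy(mr_weighted_median(h, penalized = TRUE, n_boot = 100,
                                    seed = i))$beta)
  })
  invalid_weight <- 9 * 0.45^2 / (9 * 0.45^2 + 21 * 0.3^2)
  expect_equal(invalid_weight, 0.49, tolerance = 0.01)
  expect_lt(abs(mean(res["pwm", ]) + 0.27), 0.02)
  expect_gt(abs(mean(res["ivw", ]) + 0.27), 0.02)
})

test_that("reverse MR is a relabelled IVW with correct null behaviour", {
  h <- random_hset(10, beta = 0, seed = 91)
  fwd <- tidy(mr_ivw(h))
  rev <- tidy(reverse_mr(h))
  expect_equal(rev$beta, fwd$beta)
  expect_equal(rev$direction, "reverse")
  hz <- harmonized_set(gamma = c(0.2, 0.3, 0.15), se_gamma = rep(0.02, 3),
                       Gamma = rep(0, 3), se_Gamma = rep(0.02, 3))
  expect_equal(tidy(reverse_mr(hz))$beta, 0)

  # no reverse effect: rejection near the nominal level
  cfg <- sim_config(k_snps = 4, beta_true = 0, gamma_sd = 0.1655,
                    n_exposure = 29347, n_outcome = 210088)
  set.seed(92)
  rej <- sapply(1:500, function(i) {
    cfg$seed <- i
    s <- simulate_two_sample(cfg, as = "harmonized")
    tidy(reverse_mr(s$hset))$pvalue < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("estimators are invariant to reordering and joint sign flips", {
  h <- random_hset(20, seed = 101)
  set.seed(102)
  perm <- sample(20)
  s <- sample(c(-1, 1), 20, replace = TRUE)
  h2 <- harmonized_set(gamma = (h$gamma * s)[perm],
                       se_gamma = h$se_gamma[perm],
                       Gamma = (h$Gamma * s)[perm],
                       se_Gamma = h$se_Gamma[perm])
  expect_equal(tidy(mr_ivw(h2))$beta, tidy(mr_ivw(h))$beta,
               tolerance = 1e-12)
  expect_equal(tidy(mr_egger(h2, n_boot = 0))$beta,
               tidy(mr_egger(h, n_boot = 0))$beta, tolerance = 1e-12)
  expect_equal(tidy(mr_weighted_median(h2, n_boot = 100, seed = 5))$beta,
               tidy(mr_weighted_median(h, n_boot = 100, seed = 5))$beta,
               tolerance = 1e-12)
})
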