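#' @title Synthetic consortium-scale and cohort data
#' @description
#' Generators emulating the statistical structure the MR pipeline assumes:
#' per-variant true effects observed with sampling noise at
#' consortium-scale standard errors, strictly two-sample (independent)
#' exposure and outcome draws, configurable horizontal pleiotropy
#' (balanced or directional, with optional InSIDE violation), two
#' correlated exposures with opposite causal effects, and an
#' individual-level cohort with a configurable nonlinear depot-adiponectin
#' dose-response.
#' @name synthetic_data
NULL

#' Simulation configuration for two-sample summary data
#'
#' Defaults describe the abdominal-fat scenario: 56 instruments at
#' consortium sample sizes (exposure n = 210088, outcome n = 29347) and a
#' causal effect of -0.27 SD log-adiponectin per SD of waist
#' circumference. `gamma_sd = 0.0242` makes the instrument set explain
#' about 1.2% of exposure variance.
#'
#' @param k_snps number of instruments.
#' @param beta_true causal effect, SD outcome per SD exposure.
#' @param beta2_true optional second-exposure causal effect (enables the
#'   two-exposure mode).
#' @param n_exposure,n_outcome sample sizes of the two non-overlapping
#'   GWAS samples.
#' @param maf_range range for the uniform minor-allele-frequency draw.
#' @param gamma_sd SD of the true variant-exposure effects.
#' @param gamma2_sd SD for the second exposure (defaults to `gamma_sd`).
#' @param exposure_correlation correlation between the two exposures' true
#'   variant effects, in (-1, 1).
#' @param pleiotropy list with elements `fraction_invalid` (share of
#'   variants with a direct outcome effect), `mean` and `sd` of the direct
#'   effects, `directional` (if `TRUE` the mean acts on the positive-gamma
#'   orientation; if `FALSE` direct effects are centred at zero), and
#'   `inside_violation` with `inside_slope` (direct effects gain a
#'   component proportional to instrument strength, violating InSIDE).
#' @param palindromic_fraction share of variants assigned A/T or G/C
#'   allele pairs (exercises the harmonization rules). Default 0.1.
#' @param noise_free if `TRUE`, observed betas equal the true betas
#'   (infinite-sample mode); SEs keep their finite-sample values.
#' @param seed integer seed; the same seed reproduces the draw exactly.
#' @return a `sim_config` list.
#' @export
sim_config <- function(k_snps = 56, beta_true = -0.27, beta2_true = NULL,
                       n_exposure = 210088, n_outcome = 29347,
                       maf_range = c(0.05, 0.5), gamma_sd = 0.0242,
                       gamma2_sd = NULL, exposure_correlation = 0,
                       pleiotropy = list(), palindromic_fraction = 0.1,
                       noise_free = FALSE, seed = NULL) {
  pl <- modifyList(list(fraction_invalid = 0, mean = 0, sd = 0,
                        directional = FALSE, inside_violation = FALSE,
                        inside_slope = 0.5), pleiotropy)
  cfg <- list(k_snps = k_snps, beta_true = beta_true, beta2_true = beta2_true,
              n_exposure = n_exposure, n_outcome = n_outcome,
              maf_range = maf_range, gamma_sd = gamma_sd,
              gamma2_sd = gamma2_sd %||% gamma_sd,
              exposure_correlation = exposure_correlation, pleiotropy = pl,
              palindromic_fraction = palindromic_fraction,
              noise_free = noise_free, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  pl <- cfg$pleiotropy
  if (cfg$k_snps < 1) stop("k_snps must be at least 1", call. = FALSE)
  if (cfg$n_exposure <= 0 || cfg$n_outcome <= 0) {
    stop("sample sizes must be positive", call. = FALSE)
  }
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (pl$fraction_invalid < 0 || pl$fraction_invalid > 1) {
    stop("fraction_invalid must be in [0, 1]", call. = FALSE)
  }
  if (abs(cfg$exposure_correlation) >= 1) {
    stop("exposure_correlation must be in (-1, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation scenario from a YAML file
#'
#' Key-value scenario files map directly onto [sim_config()] arguments;
#' the packaged scenarios under
#' `system.file("extdata", "scenarios", package = "depotmr")` encode the
#' consortium-scale study conditions.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("cannot read scenario file: ", path,
                               call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}

NONPAL_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                         "G", "A", "G", "T", "T", "C", "T", "G"),
                       ncol = 2, byrow = TRUE)
PAL_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                    ncol = 2, byrow = TRUE)

# latent draws shared by both output modes
sim_draw <- function(cfg) {
  k <- cfg$k_snps
  pl <- cfg$pleiotropy
  maf <- runif(k, cfg$maf_range[1], cfg$maf_range[2])
  g1 <- rnorm(k, 0, cfg$gamma_sd)
  g2 <- NULL
  if (!is.null(cfg$beta2_true)) {
    rho <- cfg$exposure_correlation
    g2 <- rho * (cfg$gamma2_sd / cfg$gamma_sd) * g1 +
      rnorm(k, 0, cfg$gamma2_sd * sqrt(1 - rho^2))
  }
  invalid <- runif(k) < pl$fraction_invalid
  alpha <- numeric(k)
  if (any(invalid)) {
    ni <- sum(invalid)
    if (pl$directional) {
      a <- rnorm(ni, pl$mean, pl$sd)
      if (pl$inside_violation) a <- a + pl$inside_slope * abs(g1[invalid])
      # the directional mean acts on the positive-gamma orientation
      alpha[invalid] <- a * sign(g1[invalid])
    } else {
      alpha[invalid] <- rnorm(ni, 0, pl$sd)
    }
  }
  Gtrue <- cfg$beta_true * g1 + alpha
  if (!is.null(g2)) Gtrue <- Gtrue + cfg$beta2_true * g2
  se_g <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exposure)
  se_G <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_outcome)
  noise <- if (cfg$noise_free) 0 else 1
  list(maf = maf, g1 = g1, g2 = g2, alpha = alpha, invalid = invalid,
       Gtrue = Gtrue, se_g = se_g, se_g2 = se_g, se_G = se_G,
       g1_hat = g1 + noise * rnorm(k, 0, se_g),
       g2_hat = if (is.null(g2)) NULL else g2 + noise * rnorm(k, 0, se_g),
       G_hat = Gtrue + noise * rnorm(k, 0, se_G))
}

sumstats_from <- function(snp, ea, oa, eaf, beta, se, n, trait) {
  as_sumstats(tibble::tibble(
    snp = snp, ea = ea, oa = oa, eaf = eaf, beta = beta, se = se,
    pvalue = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin), n = n),
    trait_name = trait)
}

#' Simulate a two-sample MR dataset
#'
#' Draws minor-allele frequencies, true variant-exposure effects
#' (bivariate across two exposures when `beta2_true` is set), direct
#' pleiotropic effects for the invalid fraction, and true outcome effects
#' `Gamma = beta_true * gamma (+ beta2_true * gamma2) + alpha`; observed
#' betas add independent Gaussian noise in each sample with the standard
#' 1/sqrt(2 p (1-p) n) standard errors for standardized traits. In
#' `"datasets"` mode the exposure and outcome tables carry randomly
#' re-oriented alleles (swaps, strand flips, palindromic pairs) so the
#' harmonization stage is exercised; `"harmonized"` mode returns the
#' allele-aligned set directly for estimator-level work.
#'
#' @param config a [sim_config()].
#' @param as `"datasets"` (default) or `"harmonized"`.
#' @return for `"datasets"`: a list with `exposure`, optionally
#'   `exposure2`, `outcome` (each `mr_sumstats`) and `truth`; for
#'   `"harmonized"`: a list with `hset` and `truth`. `truth` is a
#'   per-variant tibble of all latent values.
#' @export
simulate_two_sample <- function(config, as = c("datasets", "harmonized")) {
  as <- match.arg(as)
  validate_sim_config(config)
  with_seed(config$seed, {
    d <- sim_draw(config)
    k <- config$k_snps
    snp <- sprintf("rs%06d", seq_len(k))
    truth <- tibble::tibble(
      snp = snp, maf = d$maf, gamma_true = d$g1,
      gamma2_true = if (is.null(d$g2)) NA_real_ else d$g2,
      alpha = d$alpha, invalid = d$invalid, Gamma_true = d$Gtrue,
      se_gamma = d$se_g, se_Gamma = d$se_G)
    attr(truth, "config") <- config
    if (as == "harmonized") {
      hset <- harmonized_set(
        gamma = d$g1_hat, se_gamma = d$se_g,
        Gamma = d$G_hat, se_Gamma = d$se_G,
        gamma2 = d$g2_hat, se_gamma2 = if (is.null(d$g2)) NULL else d$se_g,
        snp = snp, eaf = d$maf, exposure_name = "exposure",
        exposure2_name = if (is.null(d$g2)) NA_character_ else "exposure2")
      return(list(hset = hset, truth = truth))
    }
    pal <- runif(k) < config$palindromic_fraction
    ppick <- sample.int(nrow(PAL_PAIRS), k, replace = TRUE)
    npick <- sample.int(nrow(NONPAL_PAIRS), k, replace = TRUE)
    ea <- ifelse(pal, PAL_PAIRS[ppick, 1], NONPAL_PAIRS[npick, 1])
    oa <- ifelse(pal, PAL_PAIRS[ppick, 2], NONPAL_PAIRS[npick, 2])
    eaf <- ifelse(runif(k) < 0.5, d$maf, 1 - d$maf)

    # re-orient the outcome (and second-exposure) representation at random
    reorient <- function(beta) {
      swap <- runif(k) < 0.5
      strand <- runif(k) < 0.5
      ea2 <- ifelse(swap, oa, ea)
      oa2 <- ifelse(swap, ea, oa)
      ea2 <- ifelse(strand, COMPLEMENT[ea2], ea2)
      oa2 <- ifelse(strand, COMPLEMENT[oa2], oa2)
      list(ea = ea2, oa = oa2, beta = ifelse(swap, -beta, beta),
           eaf = ifelse(swap, 1 - eaf, eaf))
    }
    out <- list()
    out$exposure <- sumstats_from(snp, ea, oa, eaf, d$g1_hat, d$se_g,
                                  config$n_exposure, "exposure")
    if (!is.null(d$g2)) {
      r2x <- reorient(d$g2_hat)
      out$exposure2 <- sumstats_from(snp, r2x$ea, r2x$oa, r2x$eaf, r2x$beta,
                                     d$se_g, config$n_exposure, "exposure2")
    }
    ro <- reorient(d$G_hat)
    out$outcome <- sumstats_from(snp, ro$ea, ro$oa, ro$eaf, ro$beta, d$se_G,
                                 config$n_outcome, "outcome")
    out$truth <- truth
    out
  })
}

DEPOTS <- c("visceral", "deep_scat", "superficial_scat", "gluteofemoral")

default_depot_params <- function() {
  list(male = list(mean = c(visceral = 6.8, deep_scat = 1.2,
                            superficial_scat = 0.7, gluteofemoral = 3.7),
                   sd = c(visceral = 1.9, deep_scat = 0.7,
                          superficial_scat = 0.3, gluteofemoral = 1.6)),
       female = list(mean = c(visceral = 4.9, deep_scat = 1.5,
                              superficial_scat = 1.0, gluteofemoral = 5.4),
                     sd = c(visceral = 1.6, deep_scat = 0.8,
                            superficial_scat = 0.5, gluteofemoral = 1.9)))
}

default_depot_correlations <- function() {
  m <- matrix(0.6, 4, 4, dimnames = list(DEPOTS, DEPOTS))
  m["visceral", ] <- m[, "visceral"] <- 0.4
  diag(m) <- 1
  m
}

#' Simulate an individual-level body-composition cohort
#'
#' Draws sex, four correlated fat-depot measures on their raw scales
#' (means and SDs patterned on a young-adult birth cohort: e.g. male
#' visceral fat 6.8 +/- 1.9 cm, gluteofemoral fat 3.7 +/- 1.6 kg),
#' lifestyle covariates, and standardized log-adiponectin from a linear
#' predictor over the within-sex standardized depots plus Gaussian noise.
#' An optional nonlinearity adds a mean-preserving quadratic term
#' `quad * (z^2 - 1)` in one depot's standardized value, producing a
#' U-shaped (or inverted-U) dose-response.
#'
#' @param n cohort size (default 2743, split ~48% male).
#' @param effects named vector of depot effects, SD outcome per SD depot.
#' @param depot_correlations 4x4 positive-definite correlation matrix of
#'   the depots.
#' @param depot_params per-sex list of depot means and SDs on raw scales.
#' @param covariate_effects named vector for `ancestry` (continuous
#'   fraction), `smoking`, `alcohol`, `activity` (category codes, linear
#'   in code).
#' @param nonlinearity optional list `(depot =, quad =)`.
#' @param noise_sd residual SD (default 0.93, making the outcome variance
#'   approximately 1 under the default effects).
#' @param prop_male proportion of male records.
#' @param seed integer seed.
#' @return a tibble with columns `id`, `sex`, the four depot columns (raw
#'   scale, truncated at 0.01), `ancestry`, `smoking`, `alcohol`,
#'   `activity`, `log_adiponectin`; the generating parameters are stored
#'   in the `"truth"` attribute.
#' @export
simulate_cohort <- function(n = 2743,
                            effects = c(visceral = -0.25, deep_scat = -0.10,
                                        superficial_scat = -0.20,
                                        gluteofemoral = 0.20),
                            depot_correlations = default_depot_correlations(),
                            depot_params = default_depot_params(),
                            covariate_effects = c(ancestry = -0.10,
                                                  smoking = -0.02,
                                                  alcohol = -0.03,
                                                  activity = 0.02),
                            nonlinearity = NULL, noise_sd = 0.93,
                            prop_male = 1315 / 2743, seed = NULL) {
  R <- as.matrix(depot_correlations)
  L <- tryCatch(chol(R), error = function(e) {
    stop("depot correlation matrix is not positive definite", call. = FALSE)
  })
  with_seed(seed, {
    sex <- ifelse(runif(n) < prop_male, "male", "female")
    z <- matrix(rnorm(n * 4), n, 4) %*% L
    colnames(z) <- DEPOTS
    raw <- z
    for (s in c("male", "female")) {
      i <- sex == s
      p <- depot_params[[s]]
      raw[i, ] <- sweep(sweep(z[i, , drop = FALSE], 2, p$sd[DEPOTS], "*"),
                        2, p$mean[DEPOTS], "+")
    }
    raw <- pmax(raw, 0.01)
    out <- tibble::tibble(id = seq_len(n), sex = sex)
    out <- dplyr::bind_cols(out, tibble::as_tibble(raw))
    out$ancestry <- runif(n, 0, 0.88)
    out$smoking <- sample(0:3, n, replace = TRUE,
                          prob = c(0.58, 0.18, 0.08, 0.16))
    out$alcohol <- rbinom(n, 1, 0.49)
    out$activity <- sample(0:2, n, replace = TRUE,
                           prob = c(0.49, 0.22, 0.29))
    # outcome built from within-sex standardized depot values, so a
    # standardized regression on the same data recovers `effects` exactly
    # in the noise-free case
    zs <- raw
    for (s in c("male", "female")) {
      i <- sex == s
      zs[i, ] <- apply(raw[i, , drop = FALSE], 2, std_within)
    }
    pred <- drop(zs %*% effects[DEPOTS]) +
      covariate_effects[["ancestry"]] * out$ancestry +
      covariate_effects[["smoking"]] * out$smoking +
      covariate_effects[["alcohol"]] * out$alcohol +
      covariate_effects[["activity"]] * out$activity
    if (!is.null(nonlinearity)) {
      zd <- zs[, nonlinearity$depot]
      pred <- pred + nonlinearity$quad * (zd^2 - 1)
    }
    out$log_adiponectin <- pred + rnorm(n, 0, noise_sd)
    attr(out, "truth") <- list(effects = effects,
                               covariate_effects = covariate_effects,
                               nonlinearity = nonlinearity,
                               noise_sd = noise_sd)
    out
  })
}
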