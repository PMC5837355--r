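#' @title Full-analysis pipeline and simulation studies
#' @name pipeline
NULL

#' Configuration for the full MR analysis
#'
#' Inputs may be file paths (read with [read_summary_table()] /
#' [read_ld_pairs()]) or in-memory tables.
#'
#' @param exposure,outcome summary datasets or file paths (required).
#' @param second_exposure optional second exposure for multivariable MR.
#' @param ld optional LD pair table or file path; omitted means all
#'   candidate instruments are treated as independent.
#' @param reverse_snps optional character vector of variant ids to use as
#'   instruments for the outcome trait in a reverse-direction analysis
#'   (e.g. the four ADIPOQ-region variants for adiponectin).
#' @param gwas_p genome-wide significance threshold (default 5e-8).
#' @param ld_r2 LD pruning threshold (default 0.05).
#' @param palindrome_window palindromic-ambiguity EAF window (default
#'   0.08).
#' @param flag_threshold per-variant heterogeneity flag (default
#'   `qchisq(0.95, 1)`).
#' @param variance_model IVW variance model.
#' @param penalty_scale weighted-median penalty constant.
#' @param n_boot bootstrap replicates for Egger/median CIs.
#' @param seed seed for all stochastic steps (bootstrap).
#' @param output_dir optional directory; when set, all report tables are
#'   written there as TSV files.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(exposure, outcome, second_exposure = NULL,
                            ld = NULL, reverse_snps = NULL,
                            gwas_p = 5e-8, ld_r2 = 0.05,
                            palindrome_window = 0.08,
                            flag_threshold = qchisq(0.95, 1),
                            variance_model = "fixed", penalty_scale = 20,
                            n_boot = 1000, seed = 1, output_dir = NULL) {
  stopifnot(gwas_p > 0, gwas_p <= 1, ld_r2 >= 0, ld_r2 <= 1,
            palindrome_window >= 0, palindrome_window < 0.5,
            flag_threshold > 0)
  for (nm in c("exposure", "outcome", "second_exposure", "ld")) {
    v <- get(nm)
    if (is.character(v) && !file.exists(v)) {
      stop("input path for ", nm, " does not exist: ", v, call. = FALSE)
    }
  }
  structure(list(exposure = exposure, outcome = outcome,
                 second_exposure = second_exposure, ld = ld,
                 reverse_snps = reverse_snps, gwas_p = gwas_p,
                 ld_r2 = ld_r2, palindrome_window = palindrome_window,
                 flag_threshold = flag_threshold,
                 variance_model = variance_model,
                 penalty_scale = penalty_scale, n_boot = n_boot,
                 seed = seed, output_dir = output_dir),
            class = "analysis_config")
}

load_sumstats <- function(x, trait) {
  if (is.character(x)) return(read_summary_table(x, trait_name = trait))
  if (inherits(x, "mr_sumstats")) return(x)
  as_sumstats(x, trait_name = trait)
}

run_stage <- function(name, log_env, detail, expr) {
  log_env$log <- dplyr::bind_rows(log_env$log,
                                  tibble::tibble(stage = name,
                                                 detail = detail))
  tryCatch(expr, error = function(e) {
    stop(sprintf("in stage '%s': %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full two-sample MR analysis
#'
#' Executes, in order: genome-wide significance filtering, greedy LD
#' pruning, overlap exclusion between the two exposures' instruments,
#' allele harmonization against the outcome, causal estimation (IVW,
#' multivariable IVW when a second exposure is supplied, MR-Egger,
#' weighted and penalized weighted median), stage-one diagnostics
#' (Cochran's Q / I-squared, funnel asymmetry), the single-pass
#' heterogeneous-variant removal with IVW re-estimation, and, when
#' `reverse_snps` is supplied, the reverse-direction IVW. Every threshold,
#' seed, selection and drop decision is logged.
#'
#' @param config an [analysis_config()].
#' @return an `mr_report` list: `estimates` (tidy table with an `analysis`
#'   column distinguishing primary, post-removal and reverse rows),
#'   `heterogeneity` and `asymmetry` summary tables, `forest`, `funnel`
#'   and `scatter` per-variant data, `selection` (instrument selection
#'   logs), `dropped` (harmonization drops), `removed` (heterogeneous
#'   variants), `log`, and the `config`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  lg <- new.env()
  lg$log <- tibble::tibble(stage = character(), detail = character())

  exposures <- list(load_sumstats(config$exposure, "exposure1"))
  if (!is.null(config$second_exposure)) {
    exposures[[2]] <- load_sumstats(config$second_exposure, "exposure2")
  }
  outcome <- load_sumstats(config$outcome, "outcome")
  enames <- vapply(exposures, trait_name, character(1))
  ld <- if (is.null(config$ld)) {
    ld_pairs(character(), character(), numeric())
  } else if (is.character(config$ld)) read_ld_pairs(config$ld) else config$ld

  sel <- lapply(seq_along(exposures), function(i) {
    gw <- run_stage("filter_genomewide", lg,
                    sprintf("%s: p < %g", enames[i], config$gwas_p),
                    filter_genomewide(exposures[[i]], config$gwas_p))
    run_stage("ld_prune", lg,
              sprintf("%s: r2 >= %g removed", enames[i], config$ld_r2),
              ld_prune(gw, ld, config$ld_r2))
  })
  overlap <- character()
  if (length(sel) == 2) {
    ex <- run_stage("exclude_overlap", lg, "shared instruments removed",
                    exclude_overlap(sel[[1]], sel[[2]]))
    sel <- list(ex$a, ex$b)
    overlap <- ex$overlap
  }

  estimates <- list()
  het_rows <- list()
  asym_rows <- list()
  forest <- list()
  funnel <- list()
  scatter <- list()
  removed <- list()
  dropped <- list()
  hsets <- list()

  for (i in seq_along(sel)) {
    en <- enames[i]
    hset <- run_stage("harmonize", lg, en,
                      harmonize(sel[[i]], outcome,
                                palindromic_eaf_window = config$palindrome_window))
    attr(hset, "exposure_name") <- en
    hsets[[en]] <- hset
    dropped[[en]] <- dplyr::mutate(dropped_snps(hset), exposure = en)

    est <- dplyr::bind_rows(
      mr_ivw(hset, variance_model = config$variance_model),
      mr_egger(hset, n_boot = config$n_boot, seed = config$seed),
      mr_weighted_median(hset, penalized = FALSE, n_boot = config$n_boot,
                         seed = config$seed),
      mr_weighted_median(hset, penalized = TRUE,
                         penalty_scale = config$penalty_scale,
                         n_boot = config$n_boot, seed = config$seed))
    est$analysis <- "primary"
    estimates[[length(estimates) + 1]] <- run_stage("estimate", lg, en, est)

    het <- run_stage("cochran_q", lg, en,
                     cochran_q(hset, flag_threshold = config$flag_threshold))
    het_rows[[en]] <- dplyr::mutate(glance(het), exposure = en)
    asym <- run_stage("egger_asymmetry", lg, en, egger_asymmetry_test(hset))
    asym_rows[[en]] <- dplyr::mutate(glance(asym), exposure = en)
    forest[[en]] <- dplyr::mutate(wald_ratios(hset), exposure = en)
    funnel[[en]] <- dplyr::mutate(tidy(asym), exposure = en)
    scatter[[en]] <- tibble::tibble(exposure = en, snp = hset$snp,
                                    gamma = hset$gamma,
                                    se_gamma = hset$se_gamma,
                                    Gamma = hset$Gamma,
                                    se_Gamma = hset$se_Gamma)
    rem <- run_stage("remove_heterogeneous", lg, en,
                     remove_heterogeneous_and_reestimate(
                       hset, flag_threshold = config$flag_threshold,
                       variance_model = config$variance_model))
    removed[[en]] <- dplyr::mutate(rem$removed, exposure = en)
    post <- rem$estimate
    post$analysis <- "post_removal"
    estimates[[length(estimates) + 1]] <- post
  }

  if (length(sel) == 2) {
    joint_ids <- union(sel[[1]]$snp, sel[[2]]$snp)
    joint_exp <- exposures[[1]][exposures[[1]]$snp %in% joint_ids, ]
    jset <- run_stage("harmonize_joint", lg,
                      sprintf("union of %d instruments", length(joint_ids)),
                      harmonize(new_sumstats(joint_exp, trait_name = enames[1]),
                                outcome, second_exposure = exposures[[2]],
                                palindromic_eaf_window = config$palindrome_window))
    mv <- run_stage("mv_ivw", lg, "both exposures", mr_mv_ivw(jset))
    mv$exposure <- enames
    mv$analysis <- "primary"
    estimates[[length(estimates) + 1]] <- mv
    hsets[["joint"]] <- jset
  } else if (!is.null(config$second_exposure)) {
    warn("second exposure supplied but unusable; multivariable IVW skipped")
  }

  if (!is.null(config$reverse_snps)) {
    rev_exp <- outcome[outcome$snp %in% config$reverse_snps, ]
    for (i in seq_along(exposures)) {
      rset <- run_stage("harmonize_reverse", lg, enames[i],
                        harmonize(new_sumstats(rev_exp,
                                               trait_name = trait_name(outcome)),
                                  exposures[[i]],
                                  palindromic_eaf_window = config$palindrome_window))
      rev <- run_stage("reverse_mr", lg, enames[i],
                       reverse_mr(rset, variance_model = config$variance_model))
      rev$exposure <- trait_name(outcome) %||% "outcome"
      rev$analysis <- paste0("reverse_on_", enames[i])
      estimates[[length(estimates) + 1]] <- rev
    }
  }

  report <- list(
    estimates = dplyr::bind_rows(lapply(estimates, tidy)),
    heterogeneity = dplyr::bind_rows(het_rows),
    asymmetry = dplyr::bind_rows(asym_rows),
    forest = dplyr::bind_rows(forest),
    funnel = dplyr::bind_rows(funnel),
    scatter = dplyr::bind_rows(scatter),
    selection = dplyr::bind_rows(lapply(seq_along(sel), function(i) {
      dplyr::mutate(selection_log(sel[[i]]), exposure = enames[i])
    })),
    dropped = dplyr::bind_rows(dropped),
    removed = dplyr::bind_rows(removed),
    overlap = overlap,
    hsets = hsets,
    log = lg$log,
    config = config)
  class(report) <- "mr_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write an analysis report bundle as TSV files
#' @param report an `mr_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("estimates", "heterogeneity", "asymmetry", "forest", "funnel",
            "scatter", "selection", "dropped", "removed", "log")
  for (tb in tabs) {
    readr::write_tsv(report[[tb]], file.path(dir, paste0(tb, ".tsv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("<MR analysis report>\n")
  print(x$estimates, n = 20)
  invisible(x)
}

estimate_one <- function(hset, method, variance_model, penalty_scale,
                         n_boot, seed) {
  switch(method,
         ivw = mr_ivw(hset, variance_model = variance_model),
         mv_ivw = mr_mv_ivw(hset),
         egger = mr_egger(hset, n_boot = n_boot, seed = seed),
         weighted_median = mr_weighted_median(hset, penalized = FALSE,
                                              n_boot = n_boot, seed = seed),
         penalized_weighted_median =
           mr_weighted_median(hset, penalized = TRUE,
                              penalty_scale = penalty_scale,
                              n_boot = n_boot, seed = seed),
         stop("unknown method: ", method, call. = FALSE))
}

#' Repeat simulate-and-estimate and summarise operating characteristics
#'
#' Draws `n_reps` datasets from a scenario, applies the requested
#' estimators, and reports per-method bias, empirical SE, mean estimated
#' SE, 95% CI coverage of the true effect, and rejection rate at p < 0.05.
#'
#' @param scenario a [sim_config()] or a YAML scenario path.
#' @param n_reps number of replicates.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param methods estimators to run; `"mv_ivw"` requires a two-exposure
#'   scenario and reports both coefficients.
#' @param variance_model IVW variance model.
#' @param n_boot bootstrap replicates for Egger/median CIs (kept modest by
#'   default since they are recomputed every replicate).
#' @return for `n_reps > 1`, a tibble with one row per method (times
#'   exposure), columns `method`, `exposure`, `true_beta`, `bias`,
#'   `empirical_se`, `mean_se`, `coverage`, `rejection`, `n_reps`; the
#'   per-replicate estimates are attached as attribute `"reps"`. For
#'   `n_reps = 1`, the raw estimate rows.
#' @export
run_simulation_study <- function(scenario, n_reps, seed = 1,
                                 methods = c("ivw", "egger",
                                             "weighted_median",
                                             "penalized_weighted_median"),
                                 variance_model = "fixed", n_boot = 199) {
  cfg <- if (is.character(scenario)) read_scenario(scenario) else scenario
  validate_sim_config(cfg)
  if ("mv_ivw" %in% methods && is.null(cfg$beta2_true)) {
    stop("mv_ivw requested but the scenario has no second exposure",
         call. = FALSE)
  }
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_reps))
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg$seed <- rep_seeds[r]
    sim <- simulate_two_sample(cfg, as = "harmonized")
    rows <- dplyr::bind_rows(lapply(methods, function(m) {
      tidy(estimate_one(sim$hset, m, variance_model,
                        penalty_scale = 20, n_boot = n_boot,
                        seed = rep_seeds[r]))
    }))
    rows$rep <- r
    rows
  })
  if (n_reps == 1) return(reps)
  truth <- tibble::tibble(
    exposure = c("exposure", "exposure2"),
    true_beta = c(cfg$beta_true, cfg$beta2_true %||% NA_real_))
  # the Egger intercept estimates the mean direct (pleiotropic) effect
  pl <- cfg$pleiotropy
  true_intercept <- if (pl$directional) pl$fraction_invalid * pl$mean else 0
  summary <- reps |>
    dplyr::left_join(truth, by = "exposure") |>
    dplyr::mutate(true_beta = ifelse(.data$method == "egger_intercept",
                                     true_intercept, .data$true_beta)) |>
    dplyr::group_by(.data$method, .data$exposure) |>
    dplyr::summarise(
      true_beta = .data$true_beta[1],
      bias = mean(.data$beta) - .data$true_beta[1],
      empirical_se = sd(.data$beta),
      mean_se = mean(.data$se),
      coverage = mean(.data$ci_low <= .data$true_beta[1] &
                        .data$true_beta[1] <= .data$ci_high),
      rejection = mean(.data$pvalue < 0.05),
      n_reps = dplyr::n(), .groups = "drop")
  attr(summary, "reps") <- reps
  summary
}
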