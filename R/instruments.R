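#' @title Instrument selection and strength
#' @description
#' Instrument sets are tibbles of summary-statistic rows carrying a
#' `selection_log` attribute: one record per candidate variant stating the
#' action taken (`kept` / `removed`) and why. The log is the audit trail of
#' instrument selection, exportable alongside the set.
#' @name instruments
NULL

new_instruments <- function(tbl, log, trait = NA_character_) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "selection_log") <- log
  attr(tbl, "trait_name") <- trait
  class(tbl) <- unique(c("mr_instruments", class(tbl)))
  tbl
}

#' Selection log of an instrument set
#' @param x an `mr_instruments` tibble.
#' @return tibble with columns `snp`, `action`, `reason`.
#' @export
selection_log <- function(x) attr(x, "selection_log")

#' Filter variants at a genome-wide significance threshold
#'
#' Retains variants with p-value strictly below `threshold` (default the
#' conventional genome-wide level 5e-8). Every exclusion is logged.
#'
#' @param dataset an `mr_sumstats` tibble.
#' @param threshold p-value threshold; variants with `pvalue < threshold`
#'   are retained.
#' @return an `mr_instruments` tibble (subset of `dataset` rows).
#' @export
filter_genomewide <- function(dataset, threshold = 5e-8) {
  stopifnot(nrow(dataset) > 0, threshold > 0, threshold <= 1)
  keep <- dataset$pvalue < threshold
  log <- tibble::tibble(
    snp = dataset$snp,
    action = ifelse(keep, "kept", "removed"),
    reason = ifelse(keep, sprintf("p < %g", threshold),
                    sprintf("p >= %g", threshold)))
  if (!any(keep)) warn("no variant reaches the significance threshold")
  new_instruments(dataset[keep, ], log, trait = trait_name(dataset))
}

#' Read a pairwise LD table
#'
#' Whitespace-delimited, three columns: `snp_a snp_b r2`. Unlisted pairs
#' are taken as r-squared 0; the table is treated as symmetric.
#'
#' @param path file path (a header row `snp_a snp_b r2` is optional).
#' @return a tibble with columns `snp_a`, `snp_b`, `r2`.
#' @export
read_ld_pairs <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  tbl <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tbl) < 3) stop("LD pair file needs three columns", call. = FALSE)
  names(tbl)[1:3] <- c("snp_a", "snp_b", "r2")
  if (nrow(tbl) > 0 && is.na(suppressWarnings(as.numeric(tbl$r2[1])))) {
    tbl <- tbl[-1, , drop = FALSE]   # header row
  }
  ld_pairs(tbl$snp_a, tbl$snp_b, as.numeric(tbl$r2))
}

#' Construct an LD pair table
#' @param snp_a,snp_b variant id vectors.
#' @param r2 squared correlations in `[0, 1]`.
#' @return a tibble with columns `snp_a`, `snp_b`, `r2`.
#' @export
ld_pairs <- function(snp_a, snp_b, r2) {
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) {
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(snp_a = as.character(snp_a),
                 snp_b = as.character(snp_b), r2 = as.numeric(r2))
}

# symmetric lookup matrix of r2 among `snps`; unlisted pairs are 0
ld_matrix_for <- function(snps, ld) {
  m <- matrix(0, length(snps), length(snps), dimnames = list(snps, snps))
  keep <- ld$snp_a %in% snps & ld$snp_b %in% snps
  ld <- ld[keep, , drop = FALSE]
  if (nrow(ld) > 0) {
    m[cbind(ld$snp_a, ld$snp_b)] <- pmax(m[cbind(ld$snp_a, ld$snp_b)], ld$r2)
    m[cbind(ld$snp_b, ld$snp_a)] <- pmax(m[cbind(ld$snp_b, ld$snp_a)], ld$r2)
  }
  diag(m) <- 1
  m
}

#' Greedy LD pruning of candidate instruments
#'
#' Clumping-style pruning: repeatedly keep the unprocessed variant with the
#' smallest p-value (ties broken by lexical `snp` order) and remove all
#' remaining variants with r-squared at or above `r2_threshold` against it.
#' The result is deterministic and permutation-invariant, and no retained
#' pair violates the threshold.
#'
#' @param candidates an `mr_instruments` or `mr_sumstats` tibble with a
#'   `pvalue` column.
#' @param ld an LD pair table (see [ld_pairs()]); unlisted pairs mean
#'   r-squared 0.
#' @param r2_threshold removal threshold; the conventional default 0.05
#'   removes variants in even modest LD.
#' @return an `mr_instruments` tibble; the selection log names, for each
#'   removed variant, the kept variant that caused its removal.
#' @export
ld_prune <- function(candidates, ld, r2_threshold = 0.05) {
  cand <- tibble::as_tibble(candidates)
  if (nrow(cand) == 0) {
    return(new_instruments(cand, tibble::tibble(snp = character(),
                                                action = character(),
                                                reason = character()),
                           trait = trait_name(candidates)))
  }
  ord <- order(cand$pvalue, cand$snp)
  cand <- cand[ord, ]
  m <- ld_matrix_for(cand$snp, ld)
  status <- rep(NA_character_, nrow(cand))   # NA = unprocessed
  culprit <- rep(NA_character_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!is.na(status[i])) next
    status[i] <- "kept"
    hit <- which(is.na(status) & m[i, ] >= r2_threshold)
    status[hit] <- "removed"
    culprit[hit] <- cand$snp[i]
  }
  log <- tibble::tibble(
    snp = cand$snp, action = status,
    reason = ifelse(status == "kept", "index variant",
                    sprintf("r2 >= %g with %s", r2_threshold, culprit)))
  kept <- cand[status == "kept", ]
  kept <- kept[order(match(kept$snp, candidates$snp)), ]
  new_instruments(kept, log, trait = trait_name(candidates))
}

#' Exclude variants shared between two instrument sets
#'
#' Removes from both sets every variant id appearing in both, mirroring the
#' exclusion of instruments that associate with both correlated exposures.
#'
#' @param set_a,set_b instrument tibbles (any data frame with a `snp`
#'   column).
#' @return a list with elements `a`, `b` (the reduced sets) and `overlap`
#'   (the shared ids).
#' @export
exclude_overlap <- function(set_a, set_b) {
  shared <- intersect(set_a$snp, set_b$snp)
  log_add <- function(set) {
    old <- selection_log(set) %||% tibble::tibble(snp = character(),
                                                  action = character(),
                                                  reason = character())
    drop <- set$snp %in% shared
    new <- tibble::tibble(snp = set$snp[drop], action = "removed",
                          reason = "overlaps other exposure's instruments")
    new_instruments(set[!drop, ], dplyr::bind_rows(old, new),
                    trait = trait_name(set))
  }
  list(a = log_add(set_a), b = log_add(set_b), overlap = shared)
}

#' Phenotypic variance explained by an instrument set
#'
#' For standardized traits, each biallelic variant with effect-allele
#' frequency p and per-allele effect beta explains `2 p (1 - p) beta^2` of
#' the phenotypic variance; the set total is the sum, clipped to `[0, 1]`.
#'
#' @param instruments an instrument tibble, or a character vector of
#'   variant ids to look up in `dataset`.
#' @param dataset the `mr_sumstats` tibble carrying `eaf` and `beta`
#'   (defaults to `instruments` itself when it has those columns).
#' @return the explained-variance fraction.
#' @export
variance_explained <- function(instruments, dataset = NULL) {
  if (is.character(instruments)) {
    if (is.null(dataset)) stop("dataset required when instruments are ids",
                               call. = FALSE)
    rows <- dataset[match(instruments, dataset$snp), ]
    if (anyNA(rows$snp)) {
      stop("instrument(s) not in dataset: ",
           paste(setdiff(instruments, dataset$snp), collapse = ", "),
           call. = FALSE)
    }
  } else {
    rows <- tibble::as_tibble(instruments)
  }
  if (anyNA(rows$eaf)) {
    stop("missing EAF for instrument(s): ",
         paste(rows$snp[is.na(rows$eaf)], collapse = ", "), call. = FALSE)
  }
  r2 <- sum(2 * rows$eaf * (1 - rows$eaf) * rows$beta^2)
  min(max(r2, 0), 1)
}

#' Power of a two-sample MR test
#'
#' Asymptotic two-sided power for standardized traits: the IVW z-statistic
#' is approximately normal with non-centrality
#' `|beta| * sqrt(n_outcome * r2)`, where `r2` is the variance in the
#' exposure explained by the instruments.
#'
#' @param r2 instrument strength (variance explained), in (0, 1).
#' @param n_outcome outcome-sample size.
#' @param true_beta causal effect, SD outcome per SD exposure.
#' @param alpha two-sided significance level (default 0.05).
#' @return rejection probability. Equals `alpha` at `true_beta = 0`.
#' @export
mr_power <- function(r2, n_outcome, true_beta, alpha = 0.05) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must be in (0, 1)", call. = FALSE)
  if (n_outcome <= 0) stop("n_outcome must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  zstar <- qnorm(1 - alpha / 2)
  ncp <- abs(true_beta) * sqrt(n_outcome * r2)
  pnorm(ncp - zstar) + pnorm(-ncp - zstar)
}
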