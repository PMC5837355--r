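#' @title GWAS summary-statistic tables
#' @description
#' Summary-association tables are plain tibbles with one row per variant and
#' the canonical columns `snp`, `ea` (effect allele), `oa` (other allele),
#' `eaf` (effect-allele frequency), `beta`, `se`, `pvalue`, `n`. Betas are on
#' the standardized-trait scale (SD units): trait SD per effect-allele copy
#' for an anthropometric exposure, log-adiponectin SD per copy for the
#' outcome. `eaf` and `n` may be missing (`NA`).
#' @name sumstats
NULL

CANONICAL_FIELDS <- c(snp = "SNP", ea = "EA", oa = "OA", eaf = "EAF",
                      beta = "BETA", se = "SE", pvalue = "P", n = "N")
VALID_ALLELES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

new_sumstats <- function(tbl, trait_name = NA_character_,
                         rejected = NULL, ancestry_label = NA_character_,
                         covariate_adjustments = character()) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "trait_name") <- trait_name
  attr(tbl, "rejected") <- rejected %||%
    tibble::tibble(row = integer(), snp = character(), reason = character())
  attr(tbl, "ancestry_label") <- ancestry_label
  attr(tbl, "covariate_adjustments") <- covariate_adjustments
  class(tbl) <- c("mr_sumstats", class(tbl))
  tbl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trait name of a summary dataset
#' @param x an `mr_sumstats` tibble.
#' @return a string (possibly `NA`).
#' @export
trait_name <- function(x) attr(x, "trait_name") %||% NA_character_

#' Rows rejected during validation
#' @param x an `mr_sumstats` tibble returned by [read_summary_table()] or
#'   [as_sumstats()].
#' @return a tibble with columns `row`, `snp`, `reason`.
#' @export
rejected_rows <- function(x) attr(x, "rejected")

# row-wise invariant checks; returns character reason or NA if valid
row_problem <- function(snp, ea, oa, eaf, beta, se, pvalue, n) {
  dplyr::case_when(
    is.na(snp) | snp == "" ~ "missing snp id",
    !(ea %in% VALID_ALLELES) | !(oa %in% VALID_ALLELES) ~ "invalid allele",
    ea == oa ~ "identical alleles",
    is.na(beta) ~ "missing beta",
    is.na(se) | se <= 0 ~ "nonpositive SE",
    is.na(pvalue) | pvalue <= 0 | pvalue > 1 ~ "invalid p-value",
    !is.na(eaf) & (eaf <= 0 | eaf >= 1) ~ "EAF out of (0,1)",
    !is.na(n) & n <= 0 ~ "nonpositive sample size",
    TRUE ~ NA_character_
  )
}

#' Coerce a data frame to a validated summary dataset
#'
#' Rows violating the per-variant invariants (valid A/C/G/T alleles, effect
#' allele different from the other allele, positive SE, p-value in (0,1],
#' EAF strictly inside (0,1) when present) are rejected and recorded with a
#' row-indexed reason, retrievable via [rejected_rows()]. Duplicate `snp`
#' ids keep the first occurrence with a warning.
#'
#' @param data a data frame with the canonical columns (see [sumstats]).
#' @param trait_name label for the trait the betas refer to.
#' @param ancestry_label free-text ancestry descriptor.
#' @param covariate_adjustments character vector of adjustments applied in
#'   the source GWAS (e.g. `"BMI"`).
#' @return an `mr_sumstats` tibble.
#' @export
as_sumstats <- function(data, trait_name = NA_character_,
                        ancestry_label = NA_character_,
                        covariate_adjustments = character()) {
  need <- names(CANONICAL_FIELDS)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tibble::as_tibble(data)[need]
  tbl$snp <- as.character(tbl$snp)
  tbl$ea <- toupper(as.character(tbl$ea))
  tbl$oa <- toupper(as.character(tbl$oa))
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    tbl[[col]] <- as.numeric(tbl[[col]])
  }
  reason <- row_problem(tbl$snp, tbl$ea, tbl$oa, tbl$eaf, tbl$beta,
                        tbl$se, tbl$pvalue, tbl$n)
  rejected <- tibble::tibble(row = which(!is.na(reason)),
                             snp = tbl$snp[!is.na(reason)],
                             reason = reason[!is.na(reason)])
  tbl <- tbl[is.na(reason), ]
  if (anyDuplicated(tbl$snp)) {
    dup <- duplicated(tbl$snp)
    warn(paste0("duplicate snp id(s), keeping first occurrence: ",
                paste(unique(tbl$snp[dup]), collapse = ", ")))
    tbl <- tbl[!dup, ]
  }
  if (nrow(tbl) == 0) stop("no valid rows in summary dataset", call. = FALSE)
  new_sumstats(tbl, trait_name = trait_name, rejected = rejected,
               ancestry_label = ancestry_label,
               covariate_adjustments = covariate_adjustments)
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-delimited table with a header row (delimiter
#' auto-detected) and validates it via [as_sumstats()]. The canonical header
#' is `SNP EA OA EAF BETA SE P N`; `column_map` renames other dialects, as a
#' named character vector from canonical lower-case field names (`snp`,
#' `ea`, `oa`, `eaf`, `beta`, `se`, `pvalue`, `n`) to the file's column
#' names. Missing values are read as `NA`.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping canonical field
#'   names to the file's column names.
#' @inheritParams as_sumstats
#' @return an `mr_sumstats` tibble.
#' @export
read_summary_table <- function(path, column_map = NULL,
                               trait_name = NA_character_,
                               ancestry_label = NA_character_,
                               covariate_adjustments = character()) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, na = c("NA", ""),
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_guess()))
  map <- CANONICAL_FIELDS
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(CANONICAL_FIELDS))
    if (length(bad) > 0) {
      stop("unknown canonical field(s) in column_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  missing_cols <- map[!(map %in% names(raw))]
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- raw[unname(map)]
  names(tbl) <- names(map)
  as_sumstats(tbl, trait_name = trait_name, ancestry_label = ancestry_label,
              covariate_adjustments = covariate_adjustments)
}

#' Write a summary dataset in the canonical dialect
#'
#' Tab-delimited with header `SNP EA OA EAF BETA SE P N` and `NA` for
#' missing values. Numbers are written with full round-trip precision, so
#' `write -> read -> write` is byte-identical.
#'
#' @param dataset an `mr_sumstats` tibble (or data frame with canonical
#'   columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(dataset, path) {
  out <- tibble::as_tibble(dataset)[names(CANONICAL_FIELDS)]
  names(out) <- unname(CANONICAL_FIELDS)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

# Align one dataset's records onto the exposure's allele orientation.
# Returns list(beta_mult, eaf_flip, drop_reason) vectors.
align_alleles <- function(e_ea, e_oa, e_eaf, o_ea, o_oa, o_eaf, window) {
  k <- length(e_ea)
  mult <- rep(NA_real_, k)
  reason <- rep(NA_character_, k)
  pal <- is_palindromic(e_ea, e_oa)

  same <- o_ea == e_ea & o_oa == e_oa
  swap <- o_ea == e_oa & o_oa == e_ea
  csame <- COMPLEMENT[o_ea] == e_ea & COMPLEMENT[o_oa] == e_oa
  cswap <- COMPLEMENT[o_ea] == e_oa & COMPLEMENT[o_oa] == e_ea

  # non-palindromic: letters identify orientation (after strand flip)
  idx <- !pal
  mult[idx & (same | csame)] <- 1
  mult[idx & (swap | cswap)] <- -1
  reason[idx & is.na(mult)] <- "incompatible alleles"

  # palindromic: letters are uninformative; orient by allele frequency
  idxp <- pal & (same | swap | csame | cswap)
  reason[pal & !idxp] <- "incompatible alleles"
  no_eaf <- idxp & (is.na(e_eaf) | is.na(o_eaf))
  reason[no_eaf] <- "palindrome with missing EAF"
  ambig <- idxp & !no_eaf &
    (abs(e_eaf - 0.5) <= window | abs(o_eaf - 0.5) <= window)
  reason[ambig] <- "ambiguous palindrome"
  ok <- idxp & !no_eaf & !ambig
  mult[ok] <- ifelse(sign(e_eaf[ok] - 0.5) == sign(o_eaf[ok] - 0.5), 1, -1)
  mult[!is.na(reason)] <- NA_real_
  list(mult = mult, reason = reason)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Merges exposure, outcome, and optionally a second exposure on shared
#' variant ids and expresses all betas per copy of the exposure's effect
#' allele. Swapped alleles flip the beta sign and replace EAF by 1-EAF;
#' strand complements (A<->T, C<->G) are resolved before comparison;
#' palindromic variants (A/T or G/C) are oriented by EAF agreement when both
#' frequencies lie outside `0.5 +/- palindromic_eaf_window`, and dropped
#' otherwise. Every exposure variant is either retained or listed in the
#' drop log with a reason (see [dropped_snps()]).
#'
#' @param exposure,outcome `mr_sumstats` tibbles (see [as_sumstats()]).
#' @param second_exposure optional second exposure (`mr_sumstats`), e.g. hip
#'   circumference alongside waist, for multivariable MR.
#' @param palindromic_eaf_window half-width `w` of the ambiguity band: a
#'   palindromic variant is dropped when either EAF falls inside
#'   `[0.5 - w, 0.5 + w]`. Default 0.08.
#' @return an `mr_harmonized` tibble with columns `snp`, `ea`, `oa`, `eaf`,
#'   `gamma`, `se_gamma` (exposure), optionally `gamma2`, `se_gamma2`
#'   (second exposure), `Gamma`, `se_Gamma` (outcome).
#' @export
harmonize <- function(exposure, outcome, second_exposure = NULL,
                      palindromic_eaf_window = 0.08) {
  e <- tibble::as_tibble(exposure)
  o <- tibble::as_tibble(outcome)
  dropped <- tibble::tibble(snp = character(), reason = character())

  merged <- dplyr::inner_join(
    dplyr::rename(e, gamma = "beta", se_gamma = "se"),
    dplyr::rename(o, Gamma = "beta", se_Gamma = "se"),
    by = "snp", suffix = c("", "_out"))
  absent <- setdiff(e$snp, merged$snp)
  if (length(absent) > 0) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      snp = absent, reason = "absent from outcome"))
  }
  al <- align_alleles(merged$ea, merged$oa, merged$eaf,
                      merged$ea_out, merged$oa_out, merged$eaf_out,
                      palindromic_eaf_window)
  dropped <- dplyr::bind_rows(dropped, tibble::tibble(
    snp = merged$snp[!is.na(al$reason)],
    reason = al$reason[!is.na(al$reason)]))
  merged <- merged[is.na(al$reason), ]
  merged$Gamma <- merged$Gamma * al$mult[is.na(al$reason)]

  if (!is.null(second_exposure)) {
    e2 <- tibble::as_tibble(second_exposure)
    e2 <- dplyr::rename(e2, gamma2 = "beta", se_gamma2 = "se")
    merged2 <- dplyr::inner_join(merged, e2, by = "snp",
                                 suffix = c("", "_ex2"))
    absent2 <- setdiff(merged$snp, merged2$snp)
    if (length(absent2) > 0) {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        snp = absent2, reason = "absent from second exposure"))
    }
    al2 <- align_alleles(merged2$ea, merged2$oa, merged2$eaf,
                         merged2$ea_ex2, merged2$oa_ex2, merged2$eaf_ex2,
                         palindromic_eaf_window)
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      snp = merged2$snp[!is.na(al2$reason)],
      reason = paste0(al2$reason[!is.na(al2$reason)], " (second exposure)")))
    merged2 <- merged2[is.na(al2$reason), ]
    merged2$gamma2 <- merged2$gamma2 * al2$mult[is.na(al2$reason)]
    merged <- merged2
  }
  if (nrow(merged) == 0) stop("no instruments retained after harmonization",
                              call. = FALSE)
  keep <- c("snp", "ea", "oa", "eaf", "gamma", "se_gamma",
            if (!is.null(second_exposure)) c("gamma2", "se_gamma2"),
            "Gamma", "se_Gamma")
  out <- merged[keep]
  attr(out, "dropped") <- dropped
  attr(out, "exposure_name") <- trait_name(exposure)
  attr(out, "exposure2_name") <-
    if (is.null(second_exposure)) NA_character_ else trait_name(second_exposure)
  attr(out, "outcome_name") <- trait_name(outcome)
  class(out) <- c("mr_harmonized", class(out))
  out
}

# row-subset a harmonized set, preserving its attributes
slice_hset <- function(hset, idx) {
  out <- tibble::as_tibble(hset)[idx, ]
  for (a in c("dropped", "exposure_name", "exposure2_name", "outcome_name")) {
    attr(out, a) <- attr(hset, a)
  }
  class(out) <- unique(c("mr_harmonized", class(out)))
  out
}

#' Variants dropped during harmonization
#' @param hset an `mr_harmonized` tibble.
#' @return tibble with columns `snp`, `reason` (exportable as an audit file).
#' @export
dropped_snps <- function(hset) {
  attr(hset, "dropped") %||% tibble::tibble(snp = character(),
                                            reason = character())
}

#' Construct a harmonized set directly from aligned vectors
#'
#' Convenience constructor for simulation and testing, when the betas are
#' already expressed on a common effect allele.
#'
#' @param snp variant ids (defaults to `snp_1 ... snp_k`).
#' @param gamma,se_gamma exposure betas and standard errors.
#' @param Gamma,se_Gamma outcome betas and standard errors.
#' @param gamma2,se_gamma2 optional second-exposure betas and SEs.
#' @param eaf optional effect-allele frequencies.
#' @param exposure_name,exposure2_name,outcome_name trait labels.
#' @return an `mr_harmonized` tibble.
#' @export
harmonized_set <- function(gamma, se_gamma, Gamma, se_Gamma,
                           gamma2 = NULL, se_gamma2 = NULL,
                           snp = NULL, eaf = NULL,
                           exposure_name = "exposure",
                           exposure2_name = NA_character_,
                           outcome_name = "outcome") {
  k <- length(gamma)
  stopifnot(length(se_gamma) == k, length(Gamma) == k, length(se_Gamma) == k)
  if (any(se_gamma <= 0) || any(se_Gamma <= 0)) {
    stop("standard errors must be strictly positive", call. = FALSE)
  }
  out <- tibble::tibble(
    snp = snp %||% paste0("snp_", seq_len(k)),
    ea = rep("A", k), oa = rep("G", k),
    eaf = eaf %||% rep(NA_real_, k),
    gamma = gamma, se_gamma = se_gamma)
  if (!is.null(gamma2)) {
    out$gamma2 <- gamma2
    out$se_gamma2 <- se_gamma2
  }
  out$Gamma <- Gamma
  out$se_Gamma <- se_Gamma
  attr(out, "dropped") <- tibble::tibble(snp = character(),
                                         reason = character())
  attr(out, "exposure_name") <- exposure_name
  attr(out, "exposure2_name") <- exposure2_name
  attr(out, "outcome_name") <- outcome_name
  class(out) <- c("mr_harmonized", class(out))
  out
}
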