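make_table <- function() {
  tibble::tibble(
    snp = c("rs1", "rs2", "rs3"),
    ea = c("A", "C", "T"), oa = c("G", "T", "C"),
    eaf = c(0.2, 0.45, NA), beta = c(0.03, -0.01, 0.02),
    se = c(0.004, 0.005, 0.004), pvalue = c(1e-10, 0.04, 3e-8),
    n = c(210088, 210088, NA))
}

test_that("summary tables round-trip through the canonical dialect", {
  tbl <- make_table()
  ds <- as_sumstats(tbl, trait_name = "waist")
  expect_equal(nrow(ds), 3)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(ds, f1)
  back <- read_summary_table(f1, trait_name = "waist")
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ds))
  # missing eaf/n serialized as NA
  expect_match(readLines(f1)[4], "\tNA$")
  # write -> read -> write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero-record dataset writes a header-only file", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(make_table()[0, ], f)
  expect_identical(readLines(f), "SNP\tEA\tOA\tEAF\tBETA\tSE\tP\tN")
})

test_that("invalid rows are rejected with row-indexed reasons", {
  tbl <- make_table()
  tbl$se[2] <- 0
  tbl <- dplyr::bind_rows(tbl, tibble::tibble(
    snp = "rs4", ea = "A", oa = "A", eaf = 0.3, beta = 0.01, se = 0.01,
    pvalue = 0.5, n = 100))
  ds <- as_sumstats(tbl)
  expect_equal(nrow(ds), 2)
  rej <- rejected_rows(ds)
  expect_equal(rej$reason[rej$snp == "rs2"], "nonpositive SE")
  expect_equal(rej$reason[rej$snp == "rs4"], "identical alleles")
  expect_equal(rej$row, c(2L, 4L))
  # all invalid -> error
  tbl$se <- 0
  expect_error(as_sumstats(tbl), "no valid rows")
})

test_that("column mapping resolves consortium dialects; missing columns error", {
  tbl <- make_table()
  names(tbl) <- c("MarkerName", "Allele1", "Allele2", "Freq1", "b", "SE",
                  "p", "N")
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, f, na = "NA")
  ds <- read_summary_table(f, column_map = c(
    snp = "MarkerName", ea = "Allele1", oa = "Allele2", eaf = "Freq1",
    beta = "b", se = "SE", pvalue = "p", n = "N"))
  expect_equal(ds$beta, tbl$b)
  expect_error(read_summary_table(f), "missing mandatory column")
  expect_error(read_summary_table(f, column_map = c(bogus = "b")),
               "unknown canonical field")
})

test_that("duplicate variant ids keep the first occurrence with a warning", {
  tbl <- dplyr::bind_rows(make_table(), make_table()[1, ])
  expect_warning(ds <- as_sumstats(tbl), "duplicate snp id")
  expect_equal(nrow(ds), 3)
  expect_equal(ds$beta[ds$snp == "rs1"], 0.03)
})

exp_one <- function(snp = "rs1", ea = "A", oa = "G", eaf = 0.2,
                    beta = 0.05, se = 0.01) {
  as_sumstats(tibble::tibble(snp = snp, ea = ea, oa = oa, eaf = eaf,
                             beta = beta, se = se, pvalue = 1e-9,
                             n = 1000), trait_name = "exposure")
}

test_that("harmonization aligns alleles: identity, swap, strand flip", {
  e <- exp_one()
  # identical orientation: untouched
  o1 <- exp_one(beta = 0.10, eaf = 0.21)
  h1 <- harmonize(e, o1)
  expect_equal(h1$Gamma, 0.10)
  # swapped effect/other allele: sign flip
  o2 <- exp_one(ea = "G", oa = "A", beta = 0.10, eaf = 0.79)
  h2 <- harmonize(e, o2)
  expect_equal(h2$Gamma, -0.10)
  # strand-complement representation, same orientation: untouched
  o3 <- exp_one(ea = "T", oa = "C", beta = 0.10)
  h3 <- harmonize(e, o3)
  expect_equal(h3$Gamma, 0.10)
  # strand-complement and swapped: sign flip
  o4 <- exp_one(ea = "C", oa = "T", beta = 0.10, eaf = 0.78)
  h4 <- harmonize(e, o4)
  expect_equal(h4$Gamma, -0.10)
  # irreconcilable letters: dropped with reason
  o5 <- exp_one(ea = "A", oa = "C", beta = 0.10)
  expect_error(harmonize(e, o5), "no instruments retained")
})

test_that("palindromic variants follow the EAF window rule", {
  e <- exp_one(ea = "A", oa = "T", eaf = 0.10)
  # frequencies on opposite sides of 0.5: orientation flip
  o <- exp_one(ea = "A", oa = "T", eaf = 0.88, beta = 0.10)
  h <- harmonize(e, o, palindromic_eaf_window = 0.08)
  expect_equal(h$Gamma, -0.10)
  # same side: kept as-is
  o2 <- exp_one(ea = "A", oa = "T", eaf = 0.12, beta = 0.10)
  expect_equal(harmonize(e, o2)$Gamma, 0.10)
  # outcome EAF inside the ambiguity window: dropped
  o3 <- exp_one(ea = "A", oa = "T", eaf = 0.49, beta = 0.10)
  expect_error(harmonize(e, o3), "no instruments retained")
  e2 <- dplyr::bind_rows(exp_one(), exp_one(snp = "rs2", ea = "A", oa = "T",
                                            eaf = 0.10))
  o4 <- dplyr::bind_rows(exp_one(beta = 0.1),
                         exp_one(snp = "rs2", ea = "A", oa = "T",
                                 eaf = 0.49, beta = 0.1))
  h4 <- harmonize(as_sumstats(e2), as_sumstats(o4))
  expect_equal(dropped_snps(h4)$reason, "ambiguous palindrome")
  # missing EAF on a palindrome: dropped
  o5 <- dplyr::bind_rows(exp_one(beta = 0.1),
                         exp_one(snp = "rs2", ea = "A", oa = "T",
                                 eaf = NA, beta = 0.1))
  h5 <- harmonize(as_sumstats(e2), as_sumstats(o5))
  expect_equal(dropped_snps(h5)$reason, "palindrome with missing EAF")
})

test_that("harmonization bookkeeping: every exposure variant retained or logged", {
  cfg <- sim_config(k_snps = 60, palindromic_fraction = 0.4, seed = 5)
  sim <- simulate_two_sample(cfg)
  h <- harmonize(sim$exposure, sim$outcome)
  expect_equal(nrow(h) + nrow(dropped_snps(h)), nrow(sim$exposure))
  # harmonizing an already-aligned pair changes nothing
  back_exp <- as_sumstats(tibble::tibble(
    snp = h$snp, ea = h$ea, oa = h$oa, eaf = h$eaf, beta = h$gamma,
    se = h$se_gamma, pvalue = 0.5, n = 100), trait_name = "exposure")
  back_out <- as_sumstats(tibble::tibble(
    snp = h$snp, ea = h$ea, oa = h$oa, eaf = h$eaf, beta = h$Gamma,
    se = h$se_Gamma, pvalue = 0.5, n = 100), trait_name = "outcome")
  h2 <- harmonize(back_exp, back_out)
  expect_equal(h2$Gamma, h$Gamma)
  expect_equal(h2$gamma, h$gamma)
  expect_equal(nrow(dropped_snps(h2)), 0)
})

test_that("causal estimates are invariant under per-variant allele relabelling", {
  cfg <- sim_config(k_snps = 40, palindromic_fraction = 0, seed = 9)
  sim <- simulate_two_sample(cfg)
  h_ref <- harmonize(sim$exposure, sim$outcome)
  est_ref <- tidy(mr_ivw(h_ref))$beta
  set.seed(11)
  for (rep in 1:3) {
    flip_some <- function(ds) {
      tbl <- tibble::as_tibble(ds)
      i <- runif(nrow(tbl)) < 0.5
      tmp <- tbl$ea[i]
      tbl$ea[i] <- tbl$oa[i]
      tbl$oa[i] <- tmp
      tbl$beta[i] <- -tbl$beta[i]
      tbl$eaf[i] <- 1 - tbl$eaf[i]
      as_sumstats(tbl, trait_name = trait_name(ds))
    }
    h <- harmonize(flip_some(sim$exposure), flip_some(sim$outcome))
    expect_equal(tidy(mr_ivw(h))$beta, est_ref, tolerance = 1e-12)
    expect_equal(tidy(mr_egger(h, n_boot = 0))$beta,
                 tidy(mr_egger(h_ref, n_boot = 0))$beta, tolerance = 1e-12)
  }
})
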