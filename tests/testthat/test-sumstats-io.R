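test_that("canonical and dialect-mapped tables ingest row for row", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("snp\teffect_allele\tother_allele\tbeta\tse",
               "rs1\tA\tG\t0.10\t0.02",
               "rs2\tC\tT\t-0.05\t0.01",
               "rs3\tG\tA\t0.00\t0.03"), tsv)
  v <- read_sumstats(tsv)
  expect_equal(nrow(v), 3)
  expect_equal(v$snp, c("rs1", "rs2", "rs3"))
  expect_equal(v$beta, c(0.10, -0.05, 0.00))
  expect_equal(v$se, c(0.02, 0.01, 0.03))
  expect_true(all(is.na(v$eaf)))

  # same table under foreign column names, resolved via the dialect map
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tEA\tOA\tb\tstderr",
               "rs1\tA\tG\t0.10\t0.02"), tsv2)
  v2 <- read_sumstats(tsv2, dialect = c(snp = "rsid", effect_allele = "EA",
                                        other_allele = "OA", beta = "b",
                                        se = "stderr"))
  expect_equal(v2$beta, 0.10)

  # a mandatory column that the dialect cannot resolve is a config error
  expect_error(read_sumstats(tsv2, dialect = c(snp = "nope")),
               class = "mrsum_config_error")
})

test_that("malformed rows are rejected with their line numbers, not dropped silently", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("snp\teffect_allele\tother_allele\tbeta\tse",
               "rs1\tA\tG\t0.1\t0.02",
               "rs2\tI\tG\t0.1\t0.02",     # indel code
               "rs3\tA\tG\t0.1\t-1",       # negative se
               "rs4\tA\tA\t0.1\t0.02"),    # identical alleles
             tsv)
  err <- expect_error(read_sumstats(tsv), class = "mrsum_validation_error")
  expect_match(conditionMessage(err), "line 3")
  expect_match(conditionMessage(err), "A/C/G/T")
  expect_match(conditionMessage(err), "line 4")
  expect_match(conditionMessage(err), "line 5")

  v <- suppressWarnings(read_sumstats(tsv, on_invalid = "warn"))
  expect_equal(v$snp, "rs1")
})

test_that("XLSX workbooks convert to canonical TSV and round-trip losslessly", {
  tab <- data.frame(snp = c("rs1", "rs2"), effect_allele = c("A", "C"),
                    other_allele = c("G", "T"), beta = c("0.1", "-0.2"),
                    se = c("0.02", "0.05"), stringsAsFactors = FALSE)
  xlsx <- tempfile(fileext = ".xlsx")
  write_xlsx_via_python(tab, xlsx, sheet = "instrument")
  out <- convert_xlsx(xlsx, out_dir = tempdir())
  expect_named(out, "instrument")
  got <- readr::read_tsv(out[["instrument"]], col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE)
  expect_equal(nrow(got), 2)
  expect_equal(as.data.frame(got), tab)

  # TSV -> XLSX -> TSV is an involution on the cell values
  roundtrip <- read_sumstats(out[["instrument"]])
  expect_equal(roundtrip$beta, c(0.1, -0.2))
  expect_error(convert_xlsx(tempfile(fileext = ".xlsx")), class = "mrsum_io_error")
})

test_that("allele swaps and strand flips harmonize to the exposure's effect allele", {
  exposure <- make_variants("rs1", "A", "G", beta = 0.1, se = 0.02, eaf = 0.3)
  # outcome reports the other allele: sign must flip, frequency must reflect
  outcome <- make_variants("rs1", "G", "A", beta = 0.05, se = 0.03, eaf = 0.7)
  h <- harmonize(exposure, outcome)
  expect_equal(h$data$action, "flipped_outcome")
  expect_equal(h$data$beta_out, -0.05)
  expect_equal(h$data$eaf_out, 0.3)

  # same alleles reported on the opposite strand: complement resolves, no flip
  outcome2 <- make_variants("rs1", "T", "C", beta = 0.05, se = 0.03, eaf = 0.3)
  h2 <- harmonize(exposure, outcome2)
  expect_equal(h2$data$action, "kept_as_is")
  expect_equal(h2$data$beta_out, 0.05)

  # irreconcilable alleles are dropped, with the record in the audit trail
  exposure3 <- rbind(exposure, make_variants("rs2", "A", "G", 0.2, 0.02))
  outcome3 <- rbind(outcome, make_variants("rs2", "A", "C", 0.1, 0.02))
  h3 <- harmonize(exposure3, outcome3)
  expect_equal(h3$audit$action, "dropped_incompatible")
  expect_equal(h3$audit$snp, "rs2")
})

test_that("palindromic SNPs follow the frequency-window policy", {
  pal <- function(eaf_exp, eaf_out, beta_out = 0.05) {
    h <- suppressWarnings(harmonize(
      make_variants("rs1", "A", "T", beta = 0.1, se = 0.02, eaf = eaf_exp),
      make_variants("rs1", "A", "T", beta = beta_out, se = 0.03, eaf = eaf_out)
    ))
    rbind(h$data, h$audit)
  }
  # frequency at 0.5 is uninformative: drop
  expect_equal(pal(0.50, 0.30)$action, "dropped_palindromic")
  # either frequency inside the 0.5 +/- 0.08 window: drop
  expect_equal(pal(0.55, 0.30)$action, "dropped_palindromic")
  expect_equal(pal(0.30, 0.45)$action, "dropped_palindromic")
  # missing outcome frequency: drop
  expect_equal(pal(0.30, NA)$action, "dropped_palindromic")
  # both clear of the window, same side of 0.5: kept as-is
  r <- pal(0.30, 0.32)
  expect_equal(r$action, "kept_as_is")
  expect_equal(r$beta_out, 0.05)
  # opposite sides of 0.5: the outcome study read the other strand, so flip
  r2 <- pal(0.30, 0.70)
  expect_equal(r2$action, "flipped_outcome")
  expect_equal(r2$beta_out, -0.05)
  expect_equal(r2$eaf_out, 0.30)
})

test_that("harmonization is idempotent, sign-consistent, and conserves its audit", {
  set.seed(41)
  J <- 12
  ea <- c("A", "C", "G", "T")[sample.int(4, J, replace = TRUE)]
  oa <- c(A = "G", C = "A", G = "T", T = "C")[ea]  # never palindromic
  exposure <- make_variants(sprintf("rs%d", 1:J), ea, oa,
                            beta = rnorm(J, 0.1, 0.05), se = runif(J, 0.01, 0.05),
                            eaf = runif(J, 0.1, 0.9))
  flip <- sample(c(TRUE, FALSE), J, replace = TRUE)
  strand <- sample(c(TRUE, FALSE), J, replace = TRUE)
  ea_o <- ifelse(flip, oa, ea); oa_o <- ifelse(flip, ea, oa)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ea_o <- ifelse(strand, comp[ea_o], ea_o); oa_o <- ifelse(strand, comp[oa_o], oa_o)
  beta_o <- rnorm(J, 0.02, 0.02)
  outcome <- make_variants(sprintf("rs%d", 1:J), ea_o, oa_o,
                           beta = ifelse(flip, -beta_o, beta_o),
                           se = runif(J, 0.01, 0.05),
                           eaf = ifelse(flip, 1 - exposure$eaf, exposure$eaf))

  h <- harmonize(exposure, outcome)
  expect_equal(nrow(h$data) + nrow(h$audit), J)      # audit conservation
  expect_equal(h$data$beta_out, beta_o[match(h$data$snp, outcome$snp)])

  # idempotence: feeding the harmonized effects back in changes nothing
  out_again <- make_variants(h$data$snp, exposure$effect_allele[match(h$data$snp, exposure$snp)],
                             exposure$other_allele[match(h$data$snp, exposure$snp)],
                             beta = h$data$beta_out, se = h$data$se_out,
                             eaf = h$data$eaf_out)
  h2 <- harmonize(exposure, out_again)
  expect_true(all(h2$data$action == "kept_as_is"))
  expect_equal(h2$data$beta_out, h$data$beta_out)

  # sign consistency: swapping exposure alleles and negating beta is a no-op
  exp_swapped <- exposure
  exp_swapped$effect_allele <- exposure$other_allele
  exp_swapped$other_allele <- exposure$effect_allele
  exp_swapped$beta <- -exposure$beta
  exp_swapped$eaf <- 1 - exposure$eaf
  h3 <- harmonize(exp_swapped, outcome)
  expect_equal(h3$data$beta_out / h3$data$beta_exp,
               h$data$beta_out / h$data$beta_exp)
})

test_that("reversing exposure and outcome roles gives reciprocal Wald ratios", {
  exposure <- make_variants(sprintf("rs%d", 1:5), rep("A", 5), rep("G", 5),
                            beta = c(0.12, -0.08, 0.20, 0.15, 0.05),
                            se = rep(0.02, 5), eaf = seq(0.2, 0.4, length.out = 5))
  outcome <- make_variants(sprintf("rs%d", 1:5), rep("A", 5), rep("G", 5),
                           beta = c(0.03, -0.01, 0.06, 0.02, 0.01),
                           se = rep(0.03, 5), eaf = seq(0.2, 0.4, length.out = 5))
  fwd <- wald_ratios(harmonize(exposure, outcome))
  rev <- wald_ratios(harmonize(outcome, exposure))
  expect_equal(fwd$theta, 1 / rev$theta)
})

test_that("harmonizing disjoint studies names both traits in the error", {
  e <- make_variants("rs1", "A", "G", 0.1, 0.02)
  o <- make_variants("rs2", "A", "G", 0.1, 0.02)
  err <- expect_error(harmonize(e, o, exposure_label = "bmi", outcome_label = "eoc"),
                      class = "mrsum_analysis_error")
  expect_match(conditionMessage(err), "bmi")
  expect_match(conditionMessage(err), "eoc")
})
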