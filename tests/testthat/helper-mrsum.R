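# shared builders for the test suite; all fixtures are generated in code

make_variants <- function(snp, ea, oa, beta, se, eaf = NA_real_, pval = NA_real_,
                          chrom = NA_character_, pos = NA_integer_,
                          n = NA_integer_, trait_type = "continuous") {
  tibble::tibble(
    snp = snp, chrom = chrom, pos = as.integer(pos),
    effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se, pval = pval, n = as.integer(n),
    trait_type = trait_type
  )
}

# assemble an mr_harmonized object directly from aligned effect pairs
toy_harmonized <- function(beta_exp, se_exp, beta_out, se_out,
                           eaf = NULL, n_exp = NULL, n_out = NULL,
                           trait_type = "continuous") {
  J <- length(beta_exp)
  structure(
    list(
      exposure_label = "toy_exposure", outcome_label = "toy_outcome",
      exposure_trait_type = trait_type,
      data = tibble::tibble(
        snp = sprintf("rs%03d", seq_len(J)),
        beta_exp = beta_exp, se_exp = se_exp,
        beta_out = beta_out, se_out = se_out,
        eaf_exp = eaf %||% rep(NA_real_, J),
        eaf_out = eaf %||% rep(NA_real_, J),
        pval_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
        pval_out = 2 * pnorm(-abs(beta_out / se_out)),
        n_exp = as.integer(n_exp %||% rep(NA_integer_, J)),
        n_out = as.integer(n_out %||% rep(NA_integer_, J)),
        chrom = "1", pos = as.integer(seq_len(J)),
        palindromic = FALSE, action = "kept_as_is"
      ),
      audit = tibble::tibble()
    ),
    class = "mr_harmonized"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random harmonized instance for oracle-equivalence sweeps
random_instance <- function(J, seed) {
  set.seed(seed)
  toy_harmonized(
    beta_exp = rnorm(J, 0.1, 0.03),
    se_exp = runif(J, 0.005, 0.02),
    beta_out = rnorm(J, 0.02, 0.02),
    se_out = runif(J, 0.005, 0.03)
  )
}

# write a small XLSX through the system Python's openpyxl (the independent
# writer used to exercise the XLSX -> TSV conversion)
write_xlsx_via_python <- function(tab, path, sheet = "Sheet1") {
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(tab, csv, row.names = FALSE, na = "")
  script <- sprintf('
import csv, sys
from openpyxl import Workbook
wb = Workbook(); ws = wb.active; ws.title = %s
with open(%s) as fh:
    for row in csv.reader(fh):
        ws.append(row)
wb.save(%s)
', deparse(sheet), deparse(csv), deparse(path))
  status <- system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE)
  stopifnot(file.exists(path))
  invisible(path)
}

# aligned-by-construction shortcut for simulated studies (alleles already
# match; harmonization itself is covered in its own tests)
sim_fast_h <- function(s) {
  toy_harmonized(s$exposure$beta, s$exposure$se, s$outcome$beta, s$outcome$se,
                 eaf = s$exposure$eaf,
                 n_exp = s$exposure$n, n_out = s$outcome$n)
}

# independent greedy-clumping oracle: literal restatement of the definition,
# recomputed pairwise at every step
clump_oracle <- function(variants, ld, r2_threshold, window_kb, p_threshold) {
  v <- variants[!is.na(variants$pval) & variants$pval <= p_threshold, ]
  v <- v[order(v$pval, v$snp), ]
  kept <- character(0)
  for (i in seq_len(nrow(v))) {
    ok <- TRUE
    for (k in kept) {
      pos_i <- v$pos[i]; pos_k <- v$pos[v$snp == k]
      within <- if (is.na(pos_i) || is.na(pos_k)) TRUE else
        abs(pos_i - pos_k) <= window_kb * 1000
      r2 <- if (v$snp[i] %in% rownames(ld) && k %in% rownames(ld)) ld[v$snp[i], k] else 0
      if (within && r2 > r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, v$snp[i])
  }
  kept
}

# independent weighted-median oracle: 0.5-crossing found by interpolation on
# the standardized cumulative weight curve
weighted_median_oracle <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]; ww <- w[o]
  S <- (cumsum(ww) - ww / 2) / sum(ww)
  if (S[1] >= 0.5) return(th[1])
  if (S[length(S)] < 0.5) return(th[length(th)])
  stats::approx(x = S, y = th, xout = 0.5, ties = "ordered")$y
}

# a small in-memory study grid: one multi-SNP continuous exposure, one
# binary liability exposure, one 2-SNP exposure, against two outcomes
demo_config <- function(seed = 42, n_boot = 50, liability = TRUE, n_tests = 12) {
  s1 <- simulate_summary_stats(sim_config(n_snps = 12, theta = 0.15, seed = 101))
  s2 <- simulate_summary_stats(sim_config(n_snps = 8, theta = -0.1, seed = 102,
                                          exposure_type = "binary"))
  s3 <- simulate_summary_stats(sim_config(n_snps = 2, theta = 0.2, seed = 103))
  # disambiguate snp ids across the three simulated instruments
  retag <- function(s, tag) {
    s$exposure$snp <- paste0(tag, "_", s$exposure$snp)
    s$outcome$snp <- paste0(tag, "_", s$outcome$snp)
    s
  }
  s1 <- retag(s1, "e1"); s2 <- retag(s2, "e2"); s3 <- retag(s3, "e3")
  # outcomes must cover all exposures' SNPs: pool each exposure's own outcome
  outcome_for <- function(label, tabs, shift = 0) {
    d <- dplyr::distinct(dplyr::bind_rows(tabs), snp, .keep_all = TRUE)
    d$beta <- d$beta + shift
    list(label = label, data = d)
  }
  mr_config(
    exposures = list(
      list(label = "trait_sd", data = s1$exposure, trait_type = "continuous",
           n = 100000),
      list(label = "liability_trait", data = s2$exposure, trait_type = "binary",
           liability = liability, r2 = 0.0024, n = 50000),
      list(label = "two_snp_trait", data = s3$exposure, trait_type = "continuous",
           n = 100000)
    ),
    outcomes = list(
      outcome_for("outcome_a", list(s1$outcome, s2$outcome, s3$outcome)),
      outcome_for("outcome_b", list(s1$outcome, s2$outcome, s3$outcome),
                  shift = 0.001)
    ),
    seed = seed, n_boot = n_boot, n_tests = n_tests
  )
}
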