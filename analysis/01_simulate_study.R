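#!/usr/bin/env Rscript
# Build the synthetic study: 12 risk-factor instruments (continuous traits
# and binary liability traits, instrument sizes from 2 to 40 SNPs) against 3
# ovarian-cancer-style outcomes, with known causal effects. Everything
# downstream (02-05) runs from the files this script writes.

suppressMessages(library(mrsum))

out_dir <- "results/sim_study"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# design: label, trait type, instrument size, true effect per outcome
design <- tibble::tribble(
  ~label,                ~trait_type,  ~J,  ~theta_a, ~theta_b, ~theta_c,
  "age_at_menarche",     "continuous", 30,   0.05,     0.00,     0.10,
  "age_at_menopause",    "continuous", 25,   0.02,     0.00,     0.08,
  "parity",              "continuous",  2,  -0.20,     0.00,     0.00,
  "bmi",                 "continuous", 40,   0.20,     0.00,     0.00,
  "height",              "continuous", 40,   0.02,     0.00,     0.25,
  "endometriosis",       "binary",     10,   0.25,     0.10,     1.00,
  "pcos",                "binary",     11,   0.00,    -0.30,     0.00,
  "type2_diabetes",      "binary",     10,   0.00,     0.00,     0.00,
  "smoking_score",       "continuous", 35,   0.30,     0.15,     0.00,
  "crp",                 "continuous",  8,  -0.03,    -0.10,     0.00,
  "shbg",                "continuous",  8,   0.08,     0.00,     0.00,
  "vitamin_d",           "continuous",  5,   0.02,     0.00,     0.00
)
outcomes <- c(a = "overall_carcinoma", b = "endometrioid", c = "clear_cell")

config <- list(exposures = list(), outcomes = list(), seed = 20260923,
               n_boot = 200)
pooled <- setNames(vector("list", length(outcomes)), names(outcomes))

for (i in seq_len(nrow(design))) {
  row <- design[i, ]
  base_seed <- 1000 * i
  # one instrument (true gamma, maf) per trait; every outcome GWAS observes
  # theta_o * gamma plus its own independent sampling noise
  s <- simulate_summary_stats(sim_config(
    n_snps = row$J, theta = row$theta_a,
    exposure_type = row$trait_type,
    n_exp = 150000, n_out = 63000,            # case-control scale outcome GWAS
    seed = base_seed))
  s$exposure$snp <- paste0(row$label, "_", s$exposure$snp)
  s$outcome$snp <- paste0(row$label, "_", s$outcome$snp)
  readr::write_tsv(s$exposure, file.path(out_dir, paste0(row$label, ".tsv")))
  config$exposures[[length(config$exposures) + 1]] <- list(
    label = row$label, path = paste0(row$label, ".tsv"),
    trait_type = row$trait_type, n = 150000,
    liability = row$trait_type == "binary",
    r2 = if (row$trait_type == "binary") 0.003 else NULL)

  pooled[["a"]] <- dplyr::bind_rows(pooled[["a"]], s$outcome)
  for (o in c("b", "c")) {
    set.seed(base_seed + match(o, names(outcomes)))
    tab <- s$outcome
    tab$beta <- row[[paste0("theta_", o)]] * s$truth$gamma +
      rnorm(row$J) * s$truth$se_out
    tab$pval <- 2 * pnorm(-abs(tab$beta / tab$se))
    pooled[[o]] <- dplyr::bind_rows(pooled[[o]], tab)
  }
}

for (o in names(outcomes)) {
  f <- paste0("outcome_", outcomes[o], ".tsv")
  readr::write_tsv(pooled[[o]], file.path(out_dir, f))
  config$outcomes[[length(config$outcomes) + 1]] <-
    list(label = outcomes[o], path = f)
}
yaml::write_yaml(config, file.path(out_dir, "study.yaml"))

# an LD fixture demonstrating the clumping pre-stage on a blocky region
ld <- make_ld_fixture(20, 4, 0.6)
readr::write_tsv(data.frame(snp = rownames(ld), ld, check.names = FALSE),
                 file.path(out_dir, "ld_blocks.tsv"))

cat("Simulated", nrow(design), "instruments x", length(outcomes),
    "outcomes into", out_dir, "\n")
cat("True effects span", min(unlist(design[, 4:6])), "to",
    max(unlist(design[, 4:6])), "on the log-OR scale;",
    sum(design$trait_type == "binary"), "exposures are binary liabilities.\n")
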