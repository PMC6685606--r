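#!/usr/bin/env Rscript
# The main analysis: run the full 12-exposure x 3-outcome MR grid from the
# simulated study files, apply the estimator-availability rules and evidence
# tiers, and write the printed-style tables, the long master table and
# forest plots under results/mr_report/.

suppressMessages(library(mrsum))

cfg <- read_mr_config("results/sim_study/study.yaml")
report <- run_pipeline(cfg)
paths <- write_report(report, "results/mr_report", plots = TRUE)
cat("Wrote", length(paths), "files to results/mr_report\n\n")

m <- report$master
ivw <- m[grepl("^(ivw|wald)", m$method), ]
cat("IVW estimates by evidence tier:\n")
print(table(ivw$ivw_tier, ivw$outcome))

hits <- ivw[ivw$ivw_tier != "little", ]
cat("\nAssociations with strong or suggestive evidence:\n")
for (i in seq_len(nrow(hits))) {
  cat(sprintf("  %-18s -> %-18s OR %.2f (%.2f-%.2f), p = %.2g [%s]\n",
              hits$exposure[i], hits$outcome[i], exp(hits$beta[i]),
              exp(hits$ci_low[i]), exp(hits$ci_high[i]), hits$pval[i],
              hits$ivw_tier[i]))
}

truth_null <- c("type2_diabetes")
cat("\nNull-by-construction exposure (type2_diabetes) tiers:",
    paste(ivw$ivw_tier[ivw$exposure %in% truth_null], collapse = ", "), "\n")
cat("Parity-style 2-SNP instrument reported via:",
    unique(m$method[m$exposure == "parity"]),
    "with sensitivity columns dashed in the per-outcome tables.\n")
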