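#!/usr/bin/env Rscript
# Method validation by Monte Carlo: quantify estimator bias, CI coverage and
# robustness on the synthetic generator, where the causal effect is known.
# These are the same scenario runners the test suite and acceptance script
# use; here they are summarised into a single table.

suppressMessages(library(mrsum))

res0 <- mc_no_pleiotropy(n_rep = 200, seed_base = 20260923, theta = 0.1)
res1 <- mc_directional_inside(n_rep = 200, seed_base = 20270923)
res2 <- mc_median_vs_ivw(n_rep = 200, seed_base = 20280923)

validation <- tibble::tibble(
  scenario = c(rep("no_pleiotropy", 5),
               rep("directional_inside", 4),
               rep("forty_pct_invalid", 3)),
  quantity = c("ivw_mean", "egger_mean", "median_mean", "mode_mean",
               "ivw_coverage",
               "egger_intercept", "egger_slope", "ivw_bias", "ivw_bias_predicted",
               "median_abs_bias", "ivw_abs_bias", "median_win_rate"),
  value = c(res0$ivw_mean, res0$egger_mean, res0$median_mean, res0$mode_mean,
            res0$ivw_coverage,
            res1$intercept_mean, res1$slope_mean, res1$ivw_bias_mean,
            res1$analytic_bias_mean,
            res2$median_abs_bias, res2$ivw_abs_bias, res2$median_win_rate),
  target = c(0.1, 0.1, 0.1, 0.1, 0.95,
             res1$expected_intercept, 0.1, NA, NA,
             NA, NA, NA)
)
dir.create("results", showWarnings = FALSE)
readr::write_tsv(validation, "results/method_validation.tsv")

cat("Method validation (results/method_validation.tsv):\n")
print(as.data.frame(validation), digits = 3)
cat(sprintf("\nWith no pleiotropy every estimator mean sits on theta = 0.1 and IVW CIs cover %.1f%%.\n",
            100 * res0$ivw_coverage))
cat(sprintf("Under directional pleiotropy (InSIDE) the Egger intercept recovers %.4f (target %.4f)\nwhile IVW is biased by %.3f, matching the %.3f predicted from the generative truth.\n",
            res1$intercept_mean, res1$expected_intercept,
            res1$ivw_bias_mean, res1$analytic_bias_mean))
cat(sprintf("At 40%% invalid instruments the weighted median beats IVW in %.0f%% of replicates.\n",
            100 * res2$median_win_rate))
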