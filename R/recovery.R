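#' Monte-Carlo recovery studies on the synthetic generator
#'
#' Three canned simulation studies quantify how the estimator suite behaves
#' under known data-generating conditions (J = 100 SNPs, two samples of
#' 100,000, causal effect 0.1 unless overridden):
#'
#' * `mc_no_pleiotropy()` - every SNP valid; reports each estimator's mean
#'   estimate with its Monte-Carlo SE, and the empirical coverage of the
#'   IVW 95% CI.
#' * `mc_directional_inside()` - 30% of SNPs carry directional pleiotropy
#'   (mean 0.02, SD 0.005) independent of instrument strength (InSIDE
#'   holds); reports the Egger intercept and slope means (the intercept
#'   should recover `prop_invalid * mu_alpha`, the slope the causal
#'   effect), the mean IVW bias, and the mean bias predicted analytically
#'   from the generative truth
#'   (`sum(w alpha gamma) / sum(w gamma^2)`, `w = 1/se_out^2`).
#' * `mc_median_vs_ivw()` - 40% invalid SNPs; reports how often the
#'   weighted median lands closer to the truth than IVW.
#'
#' Replicate `r` uses seed `seed_base + r`, so results are reproducible and
#' extendable.
#'
#' @param n_rep Number of simulated studies.
#' @param seed_base Base seed; replicate r runs at `seed_base + r`.
#' @param theta True causal effect.
#' @param n_snps,n_exp,n_out Design sizes passed to [sim_config()].
#' @return A one-row tibble of summary statistics (see each function's
#'   description).
#' @name mc_recovery
NULL

sim_to_h <- function(s) {
  # alleles are aligned by construction, so pair the tables directly
  structure(
    list(exposure_label = "sim_exposure", outcome_label = "sim_outcome",
         exposure_trait_type = s$exposure$trait_type[1],
         data = tibble::tibble(
           snp = s$exposure$snp,
           beta_exp = s$exposure$beta, se_exp = s$exposure$se,
           beta_out = s$outcome$beta, se_out = s$outcome$se,
           eaf_exp = s$exposure$eaf, eaf_out = s$outcome$eaf,
           pval_exp = s$exposure$pval, pval_out = s$outcome$pval,
           n_exp = s$exposure$n, n_out = s$outcome$n,
           chrom = s$exposure$chrom, pos = s$exposure$pos,
           palindromic = FALSE, action = "kept_as_is"),
         audit = tibble::tibble()),
    class = "mr_harmonized"
  )
}

#' @rdname mc_recovery
#' @export
mc_no_pleiotropy <- function(n_rep = 200, seed_base = 52000, theta = 0.1,
                             n_snps = 100, n_exp = 1e5, n_out = 1e5) {
  rows <- purrr::map_dfr(seq_len(n_rep), function(r) {
    s <- simulate_summary_stats(sim_config(
      n_snps = n_snps, theta = theta, pleiotropy = "none",
      n_exp = n_exp, n_out = n_out, seed = seed_base + r))
    h <- sim_to_h(s)
    est_ivw <- mr_ivw(h, "auto")
    est_eg <- mr_egger(h)
    tibble::tibble(
      ivw = est_ivw$beta,
      covered = est_ivw$ci_low <= theta & theta <= est_ivw$ci_high,
      egger = est_eg$beta[est_eg$method == "egger_slope"],
      median = mr_weighted_median(h, n_boot = 0)$beta,
      mode = mr_weighted_mode(h, n_boot = 0)$beta)
  })
  mc <- function(x) sd(x) / sqrt(length(x))
  tibble::tibble(
    theta = theta, n_rep = n_rep,
    ivw_mean = mean(rows$ivw), ivw_mc_se = mc(rows$ivw),
    egger_mean = mean(rows$egger), egger_mc_se = mc(rows$egger),
    median_mean = mean(rows$median), median_mc_se = mc(rows$median),
    mode_mean = mean(rows$mode), mode_mc_se = mc(rows$mode),
    ivw_coverage = mean(rows$covered))
}

#' @rdname mc_recovery
#' @param prop_invalid,mu_alpha,sigma_alpha Pleiotropy regime (see
#'   [sim_config()]).
#' @export
mc_directional_inside <- function(n_rep = 200, seed_base = 63000, theta = 0.1,
                                  prop_invalid = 0.3, mu_alpha = 0.02,
                                  sigma_alpha = 0.005, n_snps = 100,
                                  n_exp = 1e5, n_out = 1e5) {
  rows <- purrr::map_dfr(seq_len(n_rep), function(r) {
    s <- simulate_summary_stats(sim_config(
      n_snps = n_snps, theta = theta, pleiotropy = "directional",
      prop_invalid = prop_invalid, mu_alpha = mu_alpha,
      sigma_alpha = sigma_alpha, n_exp = n_exp, n_out = n_out,
      seed = seed_base + r))
    h <- sim_to_h(s)
    est_eg <- mr_egger(h)
    tr <- s$truth
    w <- 1 / tr$se_out^2
    tibble::tibble(
      intercept = est_eg$beta[est_eg$method == "egger_intercept"],
      slope = est_eg$beta[est_eg$method == "egger_slope"],
      ivw_bias = mr_ivw(h, "auto")$beta - theta,
      analytic_bias = sum(w * tr$alpha * tr$gamma) / sum(w * tr$gamma^2))
  })
  mc <- function(x) sd(x) / sqrt(length(x))
  gap <- rows$ivw_bias - rows$analytic_bias
  tibble::tibble(
    theta = theta, n_rep = n_rep, expected_intercept = prop_invalid * mu_alpha,
    intercept_mean = mean(rows$intercept), intercept_mc_se = mc(rows$intercept),
    slope_mean = mean(rows$slope), slope_mc_se = mc(rows$slope),
    ivw_bias_mean = mean(rows$ivw_bias), ivw_bias_mc_se = mc(rows$ivw_bias),
    analytic_bias_mean = mean(rows$analytic_bias),
    bias_gap_mean = mean(gap), bias_gap_mc_se = mc(gap))
}

#' @rdname mc_recovery
#' @export
mc_median_vs_ivw <- function(n_rep = 200, seed_base = 74000, theta = 0.1,
                             prop_invalid = 0.4, mu_alpha = 0.02,
                             sigma_alpha = 0.005, n_snps = 100,
                             n_exp = 1e5, n_out = 1e5) {
  rows <- purrr::map_dfr(seq_len(n_rep), function(r) {
    s <- simulate_summary_stats(sim_config(
      n_snps = n_snps, theta = theta, pleiotropy = "directional",
      prop_invalid = prop_invalid, mu_alpha = mu_alpha,
      sigma_alpha = sigma_alpha, n_exp = n_exp, n_out = n_out,
      seed = seed_base + r))
    h <- sim_to_h(s)
    tibble::tibble(
      median_bias = mr_weighted_median(h, n_boot = 0)$beta - theta,
      ivw_bias = mr_ivw(h, "auto")$beta - theta)
  })
  tibble::tibble(
    theta = theta, n_rep = n_rep,
    median_abs_bias = mean(abs(rows$median_bias)),
    ivw_abs_bias = mean(abs(rows$ivw_bias)),
    median_win_rate = mean(abs(rows$median_bias) < abs(rows$ivw_bias)))
}
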