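#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (theta_j - theta_IVW)^2` over the per-SNP Wald ratios with
#' inverse-variance weights, referred to a chi-square with `J - 1` degrees of
#' freedom. `Q / (J - 1)` is exactly the overdispersion factor used by the
#' multiplicative random-effects IVW model.
#'
#' @param data An `mr_harmonized` object with at least 2 SNPs.
#' @param se_order Wald-ratio SE order.
#' @return A one-row tibble: `Q`, `df`, `pval`, `phi`.
#' @export
cochran_q <- function(data, se_order = "first") {
  wr <- wald_ratios(data, se_order = se_order)
  J <- nrow(wr)
  if (J < 2) {
    abort("Cochran's Q needs at least 2 SNPs", class = "mrsum_method_unavailable")
  }
  beta <- sum(wr$weight * wr$theta) / sum(wr$weight)
  Q <- sum(wr$weight * (wr$theta - beta)^2)
  tibble::tibble(Q = Q, df = J - 1L,
                 pval = pchisq(Q, df = J - 1, lower.tail = FALSE),
                 phi = Q / (J - 1))
}

#' Leave-one-out re-estimation
#'
#' Re-fits the IVW model (auto fixed/random selection applied to the reduced
#' SNP count) once per excluded SNP, to flag estimates driven by a single
#' influential variant.
#'
#' @param data An `mr_harmonized` object with at least 3 SNPs.
#' @param se_order Wald-ratio SE order.
#' @return An object of class `mr_loo`: list with `loo` (one row per excluded
#'   SNP: `excluded_snp` plus the estimate columns) and `full` (the all-SNP
#'   estimate).
#' @export
leave_one_out <- function(data, se_order = "first") {
  d <- if (inherits(data, "mr_harmonized")) data$data else data
  J <- nrow(d)
  if (J < 3) {
    abort("leave-one-out needs at least 3 SNPs", class = "mrsum_method_unavailable")
  }
  rows <- purrr::map(seq_len(J), function(i) {
    est <- mr_ivw(d[-i, , drop = FALSE], "auto", se_order = se_order)
    dplyr::bind_cols(tibble::tibble(excluded_snp = d$snp[i]), est)
  })
  structure(
    list(loo = dplyr::bind_rows(rows),
         full = mr_ivw(d, "auto", se_order = se_order)),
    class = "mr_loo"
  )
}

#' @export
print.mr_loo <- function(x, ...) {
  cat("Leave-one-out IVW analysis over", nrow(x$loo), "SNPs\n")
  cat("  full estimate:", format(x$full$beta, digits = 4),
      "(se", format(x$full$se, digits = 4), ")\n")
  rng <- range(x$loo$beta)
  cat("  leave-one-out range: [", format(rng[1], digits = 4), ",",
      format(rng[2], digits = 4), "]\n")
  invisible(x)
}

# per-SNP variance explained in one trait
snp_r2 <- function(beta, se, eaf, n, method) {
  if (method == "from_eaf_beta") {
    if (anyNA(eaf)) abort("from_eaf_beta needs eaf for every SNP", class = "mrsum_analysis_error")
    2 * eaf * (1 - eaf) * beta^2
  } else {
    if (anyNA(n)) abort("from_z_and_n needs a sample size for every SNP", class = "mrsum_analysis_error")
    z2 <- (beta / se)^2
    z2 / (z2 + n)
  }
}

#' Steiger directionality test
#'
#' Compares the variance the instrument SNPs explain in the exposure with the
#' variance they explain in the outcome: a valid instrument should explain
#' more of its exposure. Per-SNP r-squared is computed either from allele
#' frequency and beta (`2 p (1-p) beta^2`, continuous traits on the SD scale)
#' or from the z-statistic and sample size (`z^2 / (z^2 + n)`, the
#' approximation used for binary traits whose liability-scale inputs are
#' unavailable). The two instrument-trait correlations, estimated in
#' independent samples, are compared with a Fisher-z two-sample statistic.
#'
#' @param data An `mr_harmonized` object.
#' @param n_exp,n_out Sample sizes of the exposure and outcome GWAS (defaults
#'   taken from per-SNP `n` columns when present).
#' @param r2_method `"from_eaf_beta"` or `"from_z_and_n"`, applied per trait
#'   as `c(exposure_method, outcome_method)`; a single value is recycled.
#' @return A list with `global` (one-row tibble: `r2_exposure`, `r2_outcome`,
#'   `direction_exposure_to_outcome`, `steiger_p`) and `per_snp` (per-SNP
#'   r-squared and direction flags).
#' @export
steiger <- function(data, n_exp = NULL, n_out = NULL,
                    r2_method = "from_z_and_n") {
  d <- if (inherits(data, "mr_harmonized")) data$data else data
  r2_method <- rep(match.arg(r2_method, c("from_eaf_beta", "from_z_and_n"),
                             several.ok = TRUE), length.out = 2)
  n_exp <- n_exp %||% suppressWarnings(max(d$n_exp, na.rm = TRUE))
  n_out <- n_out %||% suppressWarnings(max(d$n_out, na.rm = TRUE))
  if (!is.finite(n_exp) || !is.finite(n_out) || n_exp <= 3 || n_out <= 3) {
    abort("steiger needs exposure and outcome sample sizes > 3", class = "mrsum_analysis_error")
  }
  n_e <- d$n_exp %||% rep(n_exp, nrow(d))
  n_o <- d$n_out %||% rep(n_out, nrow(d))
  n_e[is.na(n_e)] <- n_exp
  n_o[is.na(n_o)] <- n_out
  r2_exp <- snp_r2(d$beta_exp, d$se_exp, d$eaf_exp, n_e, r2_method[1])
  r2_out <- snp_r2(d$beta_out, d$se_out, d$eaf_out, n_o, r2_method[2])

  per_snp <- tibble::tibble(
    snp = d$snp, r2_exposure = r2_exp, r2_outcome = r2_out,
    direction_exposure_to_outcome = r2_exp > r2_out
  )
  R2e <- min(sum(r2_exp), 1 - 1e-12)
  R2o <- min(sum(r2_out), 1 - 1e-12)
  z <- (atanh(sqrt(R2e)) - atanh(sqrt(R2o))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  global <- tibble::tibble(
    snp = "global", r2_exposure = R2e, r2_outcome = R2o,
    direction_exposure_to_outcome = R2e > R2o,
    steiger_p = z_pval(z)
  )
  list(global = global, per_snp = per_snp)
}
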