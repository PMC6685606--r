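mr_estimate <- function(method, beta, se, pval, nsnp, scale = "per unit exposure",
                        ci_low = NULL, ci_high = NULL, phi = NA_real_, df = NA_integer_) {
  tibble::tibble(
    method = method, nsnp = as.integer(nsnp),
    beta = beta, se = se,
    ci_low = ci_low %||% (beta - 1.96 * se),
    ci_high = ci_high %||% (beta + 1.96 * se),
    pval = pval, phi = phi, df = as.integer(df), scale = scale
  )
}

#' Per-SNP Wald ratios
#'
#' The Wald ratio for one SNP is the outcome effect divided by the exposure
#' effect. Its first-order standard error is `se_out / |beta_exp|`; the
#' second-order (delta-method) form adds the exposure-side term
#' `beta_out^2 se_exp^2 / beta_exp^4`.
#'
#' @param data An `mr_harmonized` object (or its `data` tibble).
#' @param se_order `"first"` (default) or `"second"`.
#' @return A tibble with `snp`, `theta`, `se_theta` and inverse-variance
#'   `weight`.
#' @export
wald_ratios <- function(data, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  d <- if (inherits(data, "mr_harmonized")) data$data else data
  if (any(d$beta_exp == 0)) {
    abort(paste0("degenerate instrument (beta_exp = 0): ",
                 paste(d$snp[d$beta_exp == 0], collapse = ", ")),
          class = "mrsum_analysis_error")
  }
  theta <- d$beta_out / d$beta_exp
  se_theta <- switch(se_order,
    first = d$se_out / abs(d$beta_exp),
    second = sqrt(d$se_out^2 / d$beta_exp^2 +
                  d$beta_out^2 * d$se_exp^2 / d$beta_exp^4)
  )
  tibble::tibble(snp = d$snp, theta = theta, se_theta = se_theta,
                 weight = se_theta^-2)
}

#' Inverse-variance-weighted causal estimate
#'
#' The IVW estimate is the precision-weighted mean of the per-SNP Wald ratios,
#' equivalently the slope of an origin-constrained weighted regression of
#' outcome on exposure effects. The fixed-effects standard error is
#' `(sum w)^-1/2`; the multiplicative random-effects model inflates it by
#' `sqrt(max(1, phi))` where `phi = Q / (J - 1)` is the overdispersion implied
#' by Cochran's Q, so random-effects SEs never fall below fixed-effects ones.
#' `effects = "auto"` applies the convention used throughout this package:
#' fixed effects for 2-3 SNPs, multiplicative random effects above 3, and the
#' single-SNP Wald ratio for J = 1.
#'
#' @param data An `mr_harmonized` object.
#' @param effects `"auto"`, `"fixed"` or `"random"`.
#' @param se_order Wald-ratio SE order, see [wald_ratios()].
#' @return A one-row estimate tibble (`method`, `nsnp`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `phi`, `df`, `scale`).
#' @export
mr_ivw <- function(data, effects = c("auto", "fixed", "random"),
                   se_order = "first") {
  effects <- match.arg(effects)
  wr <- wald_ratios(data, se_order = se_order)
  J <- nrow(wr)
  if (J == 1) {
    return(mr_estimate("wald_single", wr$theta, wr$se_theta,
                       z_pval(wr$theta / wr$se_theta), 1L))
  }
  w <- wr$weight
  beta <- sum(w * wr$theta) / sum(w)
  se_fixed <- sum(w)^-0.5
  Q <- sum(w * (wr$theta - beta)^2)
  phi <- Q / (J - 1)
  if (effects == "auto") effects <- if (J <= 3) "fixed" else "random"
  se <- if (effects == "random") se_fixed * sqrt(max(1, phi)) else se_fixed
  mr_estimate(paste0("ivw_", effects), beta, se, z_pval(beta / se), J, phi = phi)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects *with* an
#' intercept, each SNP first oriented so its exposure effect is positive and
#' weighted by `1 / se_out^2`. The slope estimates the causal effect under
#' the InSIDE assumption; the intercept estimates average directional
#' pleiotropy, and a non-zero intercept flags a biased IVW estimate.
#' Standard errors are inflated by `sqrt(max(1, phi))` with `phi` the
#' weighted residual mean square; inference uses a t reference with `J - 2`
#' degrees of freedom.
#'
#' @param data An `mr_harmonized` object with at least 3 SNPs.
#' @return A two-row estimate tibble (`egger_slope`, `egger_intercept`), or a
#'   zero-row tibble carrying attribute `unavailable` when J < 3.
#' @export
mr_egger <- function(data) {
  d <- if (inherits(data, "mr_harmonized")) data$data else data
  J <- nrow(d)
  if (J < 3) return(method_unavailable("egger", J, min_snps = 3))
  flip <- sign(d$beta_exp)
  flip[flip == 0] <- 1
  x <- d$beta_exp * flip
  y <- d$beta_out * flip
  w <- d$se_out^-2

  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  denom <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / sw
  resid <- y - intercept - slope * x
  phi <- sum(w * resid^2) / (J - 2)
  infl <- max(1, phi)
  se_slope <- sqrt(infl * sw / denom)
  se_int <- sqrt(infl * sxx / denom)
  tq <- qt(0.975, df = J - 2)

  dplyr::bind_rows(
    mr_estimate("egger_slope", slope, se_slope, t_pval(slope / se_slope, J - 2), J,
                ci_low = slope - tq * se_slope, ci_high = slope + tq * se_slope,
                phi = phi, df = J - 2),
    mr_estimate("egger_intercept", intercept, se_int,
                t_pval(intercept / se_int, J - 2), J,
                ci_low = intercept - tq * se_int, ci_high = intercept + tq * se_int,
                phi = phi, df = J - 2)
  )
}

# zero-row estimate signalling a method that needs more SNPs than available
method_unavailable <- function(method, nsnp, min_snps) {
  out <- mr_estimate(character(0), numeric(0), numeric(0), numeric(0), integer(0))
  attr(out, "unavailable") <- list(method = method, nsnp = nsnp, min_snps = min_snps)
  out
}

#' Is an estimate a method-unavailable marker?
#' @param x An estimate tibble.
#' @return `TRUE` for the zero-row marker returned when too few SNPs exist.
#' @export
is_unavailable <- function(x) !is.null(attr(x, "unavailable"))

# weighted-median point estimate on ordered ratios
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  S <- (cumsum(w) - w / 2) / sum(w)
  if (S[1] >= 0.5) return(theta[1])
  J <- length(theta)
  if (S[J] < 0.5) return(theta[J])
  k <- max(which(S < 0.5))
  theta[k] + (theta[k + 1] - theta[k]) * (0.5 - S[k]) / (S[k + 1] - S[k])
}

# parametric bootstrap SE shared by the median and mode estimators:
# redraw both betas from normals at their SEs, recompute the point estimate
bootstrap_se <- function(d, point_fun, n_boot, seed, se_order) {
  set.seed(seed)
  J <- nrow(d)
  reps <- vapply(seq_len(n_boot), function(b) {
    be <- rnorm(J, d$beta_exp, d$se_exp)
    bo <- rnorm(J, d$beta_out, d$se_out)
    be[be == 0] <- .Machine$double.eps
    theta <- bo / be
    se_theta <- if (se_order == "first") d$se_out / abs(be) else
      sqrt(d$se_out^2 / be^2 + bo^2 * d$se_exp^2 / be^4)
    point_fun(theta, se_theta^-2)
  }, numeric(1))
  sd(reps)
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios: ratios are ordered and the
#' estimate interpolates between the two ratios whose standardized cumulative
#' weights bracket one half. It is consistent when at least half the total
#' weight comes from valid instruments. The standard error comes from a
#' parametric bootstrap (betas redrawn from normals at their reported SEs).
#'
#' @param data An `mr_harmonized` object with at least 3 SNPs.
#' @param n_boot Bootstrap replicates (default 1000); 0 skips the bootstrap
#'   and returns `NA` SE/CI/p (point estimate only).
#' @param seed Seed for the bootstrap; required when `n_boot > 0`.
#' @param se_order Wald-ratio SE order.
#' @return A one-row estimate tibble, or an unavailable marker when J < 3.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL, se_order = "first") {
  d <- if (inherits(data, "mr_harmonized")) data$data else data
  J <- nrow(d)
  if (J < 3) return(method_unavailable("weighted_median", J, min_snps = 3))
  wr <- wald_ratios(d, se_order = se_order)
  beta <- weighted_median_point(wr$theta, wr$weight)
  if (n_boot == 0) {
    return(mr_estimate("weighted_median", beta, NA_real_, NA_real_, J,
                       ci_low = NA_real_, ci_high = NA_real_))
  }
  if (is.null(seed)) abort("a bootstrap seed is required", class = "mrsum_config_error")
  se <- bootstrap_se(d, weighted_median_point, n_boot, seed, se_order)
  mr_estimate("weighted_median", beta, se, z_pval(beta / se), J)
}

# weighted-mode point estimate: argmax of a weighted normal-kernel density
weighted_mode_point <- function(theta, w, phi_bandwidth = 1, n_grid = 512) {
  s <- sd(theta)
  madraw <- median(abs(theta - median(theta)))
  h <- phi_bandwidth * 0.9 * min(s, madraw / 0.6745) * length(theta)^(-1/5)
  if (!is.finite(h) || h <= 0) return(theta[1])  # all ratios identical
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = n_grid)
  wn <- w / sum(w)
  dens <- as.vector(dnorm(outer(grid, theta, "-"), sd = h) %*% wn)
  grid[which.max(dens)]
}

#' Weighted-mode causal estimate
#'
#' Smooths the per-SNP Wald ratios with a weighted normal-kernel density
#' (modified Silverman bandwidth `0.9 min(sd, mad/0.6745) J^(-1/5)`, tunable
#' through `phi_bandwidth`) and takes the density argmax over a 512-point
#' grid. It is consistent when the valid instruments form the largest
#' homogeneous cluster of ratios, even if they carry under half the weight.
#' SEs use the same parametric bootstrap as [mr_weighted_median()].
#'
#' @param data An `mr_harmonized` object with at least 5 SNPs.
#' @param phi_bandwidth Bandwidth tuning multiplier (default 1).
#' @param n_boot,seed,se_order As in [mr_weighted_median()].
#' @return A one-row estimate tibble, or an unavailable marker when J < 5.
#' @export
mr_weighted_mode <- function(data, phi_bandwidth = 1, n_boot = 1000,
                             seed = NULL, se_order = "first") {
  d <- if (inherits(data, "mr_harmonized")) data$data else data
  J <- nrow(d)
  if (J < 5) return(method_unavailable("weighted_mode", J, min_snps = 5))
  wr <- wald_ratios(d, se_order = se_order)
  beta <- weighted_mode_point(wr$theta, wr$weight, phi_bandwidth)
  if (n_boot == 0) {
    return(mr_estimate("weighted_mode", beta, NA_real_, NA_real_, J,
                       ci_low = NA_real_, ci_high = NA_real_))
  }
  if (is.null(seed)) abort("a bootstrap seed is required", class = "mrsum_config_error")
  se <- bootstrap_se(d, function(th, w) weighted_mode_point(th, w, phi_bandwidth),
                     n_boot, seed, se_order)
  mr_estimate("weighted_mode", beta, se, z_pval(beta / se), J)
}

#' @importFrom stats dnorm
NULL

#' Rescale a binary-exposure estimate to the liability-odds scale
#'
#' A two-sample MR estimate for a binary exposure is expressed per unit
#' increase in the log odds of (liability to) the exposure. Multiplying the
#' log-OR, its SE and CI bounds by `ln(odds_factor)` re-expresses it per
#' `odds_factor`-fold increase in the odds — e.g. per 50% higher odds
#' liability with the default 1.5. The z-statistic, hence the p-value, is
#' unchanged.
#'
#' @param est A one-or-more-row estimate tibble on the per-log-odds scale.
#' @param odds_factor Multiplicative odds increase to scale to (default 1.5).
#' @return The rescaled estimate tibble with an updated `scale` descriptor.
#' @export
scale_liability <- function(est, odds_factor = 1.5) {
  if (odds_factor <= 0) abort("odds_factor must be positive", class = "mrsum_domain_error")
  # the Egger intercept lives on the outcome scale, not per exposure unit,
  # so it is exempt from the rescaling
  k <- ifelse(est$method == "egger_intercept", 1, log(odds_factor))
  est$beta <- est$beta * k
  est$se <- est$se * k
  est$ci_low <- est$ci_low * k
  est$ci_high <- est$ci_high * k
  est$scale <- ifelse(
    est$method == "egger_intercept", est$scale,
    sprintf("per %d%% higher odds liability", round(100 * (odds_factor - 1))))
  est
}

#' Run every available estimator on a harmonized dataset
#'
#' Applies the method-availability conventions: single-SNP Wald ratio at
#' J = 1; IVW (fixed for 2-3 SNPs, multiplicative random effects above 3);
#' MR-Egger and weighted median from 3 SNPs; weighted mode from 5.
#'
#' @param data An `mr_harmonized` object.
#' @param n_boot,seed Bootstrap settings for the median/mode estimators.
#' @param se_order Wald-ratio SE order.
#' @param phi_bandwidth Mode bandwidth multiplier.
#' @return An estimate tibble with one row per available method.
#' @export
mr_all <- function(data, n_boot = 1000, seed = NULL, se_order = "first",
                   phi_bandwidth = 1) {
  out <- list(mr_ivw(data, "auto", se_order = se_order))
  eg <- mr_egger(data)
  wm <- mr_weighted_median(data, n_boot = n_boot, seed = seed, se_order = se_order)
  mo <- mr_weighted_mode(data, phi_bandwidth = phi_bandwidth, n_boot = n_boot,
                         seed = seed, se_order = se_order)
  for (e in list(eg, wm, mo)) if (!is_unavailable(e)) out <- c(out, list(e))
  dplyr::bind_rows(out)
}
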