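test_that("Wald ratios scale effects and propagate both SE orders", {
  h <- toy_harmonized(beta_exp = 0.5, se_exp = 0.02, beta_out = 0.1, se_out = 0.05)
  wr <- wald_ratios(h)
  expect_equal(wr$theta, 0.2)
  expect_equal(wr$se_theta, 0.1)
  expect_equal(wr$weight, 100)

  wr2 <- wald_ratios(h, se_order = "second")
  expect_equal(wr2$se_theta,
               sqrt(0.05^2 / 0.5^2 + 0.1^2 * 0.02^2 / 0.5^4))  # delta method

  h0 <- toy_harmonized(0.5, 0.02, 0, 0.05)
  wr0 <- wald_ratios(h0)
  expect_equal(wr0$theta, 0)
  expect_gt(wr0$se_theta, 0)

  expect_error(wald_ratios(toy_harmonized(0, 0.02, 0.1, 0.05)),
               class = "mrsum_analysis_error")
})

test_that("IVW reduces to the shared ratio under zero heterogeneity and floors phi", {
  h <- toy_harmonized(c(0.5, 0.25), c(0.02, 0.02), c(0.1, 0.05), c(0.05, 0.025))
  fixed <- mr_ivw(h, "fixed")
  random <- mr_ivw(h, "random")
  expect_equal(fixed$beta, 0.2)
  expect_equal(random$beta, 0.2)
  expect_equal(random$se, fixed$se)       # phi floored at 1 when Q = 0
  expect_equal(fixed$phi, 0)

  # auto selection: fixed at 2-3 SNPs, random above, Wald ratio at 1
  expect_equal(mr_ivw(h, "auto")$method, "ivw_fixed")
  h4 <- random_instance(4, seed = 1)
  expect_equal(mr_ivw(h4, "auto")$method, "ivw_random")
  h1 <- toy_harmonized(0.5, 0.02, 0.1, 0.05)
  expect_equal(mr_ivw(h1)$method, "wald_single")
  expect_equal(mr_ivw(h1)$beta, 0.2)

  # random-effects SE never undercuts fixed-effects SE
  for (seed in 1:10) {
    hi <- random_instance(8, seed = 100 + seed)
    expect_gte(mr_ivw(hi, "random")$se, mr_ivw(hi, "fixed")$se)
    expect_equal(mr_ivw(hi, "random")$beta, mr_ivw(hi, "fixed")$beta)
  }
})

test_that("IVW equals the origin-constrained WLS slope on random instances", {
  for (seed in 1:100) {
    J <- sample(3:20, 1)
    h <- random_instance(J, seed = seed)
    est <- mr_ivw(h, "fixed")
    fit <- lm(beta_out ~ 0 + beta_exp, data = h$data, weights = 1 / h$data$se_out^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact affine relation and matches the WLS oracle", {
  # points exactly on beta_out = 0.05 + 0.3 * beta_exp: zero residual fit
  x <- c(0.1, 0.15, 0.2, 0.3)
  h <- toy_harmonized(x, rep(0.01, 4), 0.05 + 0.3 * x, rep(0.02, 4))
  eg <- mr_egger(h)
  expect_equal(eg$beta[eg$method == "egger_slope"], 0.3)
  expect_equal(eg$beta[eg$method == "egger_intercept"], 0.05)
  expect_equal(eg$phi[1], 0)

  for (seed in 1:100) {
    J <- sample(3:20, 1)
    h <- random_instance(J, seed = 2000 + seed)
    eg <- mr_egger(h)
    d <- h$data
    flip <- sign(d$beta_exp)
    fit <- lm(I(beta_out * flip) ~ I(beta_exp * flip), data = d,
              weights = 1 / d$se_out^2)
    co <- summary(fit)$coefficients
    expect_equal(eg$beta[eg$method == "egger_slope"], unname(co[2, 1]),
                 tolerance = 1e-10)
    expect_equal(eg$beta[eg$method == "egger_intercept"], unname(co[1, 1]),
                 tolerance = 1e-10)
    # the only SE difference is the floor at phi = 1
    phi <- eg$phi[1]
    infl <- sqrt(max(1, phi) / phi)
    expect_equal(eg$se[eg$method == "egger_slope"], unname(co[2, 2]) * infl,
                 tolerance = 1e-8)
  }

  expect_true(is_unavailable(mr_egger(toy_harmonized(c(0.1, 0.2), c(0.01, 0.01),
                                                     c(0.02, 0.04), c(0.02, 0.02)))))
})

test_that("Egger with its intercept pinned to zero is the IVW estimate", {
  for (seed in 1:20) {
    h <- random_instance(10, seed = 3000 + seed)
    d <- h$data
    flip <- sign(d$beta_exp)
    x <- d$beta_exp * flip; y <- d$beta_out * flip; w <- 1 / d$se_out^2
    slope0 <- sum(w * x * y) / sum(w * x^2)
    expect_equal(slope0, mr_ivw(h, "fixed")$beta, tolerance = 1e-12)
  }
})

test_that("the weighted median interpolates the 0.5 weight crossing", {
  # equal weights, 3 ratios: the middle order statistic
  h <- toy_harmonized(rep(1, 3), rep(0.01, 3), c(0.1, 0.2, 0.9), rep(0.05, 3))
  est <- mr_weighted_median(h, n_boot = 200, seed = 7)
  expect_equal(est$beta, 0.2)
  expect_equal(est$pval, 2 * pnorm(-abs(est$beta / est$se)))

  # identical ratios collapse to that ratio with a tiny bootstrap SE
  h2 <- toy_harmonized(rep(1, 4), rep(0.001, 4), rep(0.3, 4), rep(0.001, 4))
  est2 <- mr_weighted_median(h2, n_boot = 200, seed = 7)
  expect_equal(est2$beta, 0.3)
  expect_lt(est2$se, 0.01)

  # unequal weights match the independent interpolation oracle
  for (seed in 1:100) {
    J <- sample(3:20, 1)
    h <- random_instance(J, seed = 4000 + seed)
    wr <- wald_ratios(h)
    est <- mr_weighted_median(h, n_boot = 0)
    expect_equal(est$beta, weighted_median_oracle(wr$theta, wr$weight),
                 tolerance = 1e-12)
  }
  expect_true(is_unavailable(mr_weighted_median(toy_harmonized(1, 0.01, 0.1, 0.05))))
})

test_that("the weighted mode tracks the dominant ratio cluster", {
  # degenerate density: all ratios equal
  h <- toy_harmonized(rep(1, 5), rep(0.001, 5), rep(0.3, 5), rep(0.001, 5))
  est <- mr_weighted_mode(h, n_boot = 100, seed = 5)
  expect_equal(est$beta, 0.3)

  # a tight 6-SNP cluster near 0.2 with 2 outliers at 1.5: the mode stays in
  # the cluster while IVW is pulled upward
  theta <- c(0.19, 0.195, 0.2, 0.2, 0.205, 0.21, 1.5, 1.5)
  h2 <- toy_harmonized(rep(1, 8), rep(0.01, 8), theta, rep(0.03, 8))
  mode_est <- mr_weighted_mode(h2, n_boot = 0)
  ivw_est <- mr_ivw(h2, "fixed")
  expect_gt(mode_est$beta, 0.18)
  expect_lt(mode_est$beta, 0.22)
  expect_lt(mode_est$beta, ivw_est$beta)

  expect_true(is_unavailable(mr_weighted_mode(random_instance(4, 1))))
})

test_that("median and mode estimates stay inside the Wald-ratio range", {
  for (seed in 1:30) {
    J <- sample(5:15, 1)
    h <- random_instance(J, seed = 5000 + seed)
    wr <- wald_ratios(h)
    med <- mr_weighted_median(h, n_boot = 0)$beta
    mod <- mr_weighted_mode(h, n_boot = 0)$beta
    expect_gte(med, min(wr$theta)); expect_lte(med, max(wr$theta))
    expect_gte(mod, min(wr$theta)); expect_lte(mod, max(wr$theta))
  }
})

test_that("every estimator is invariant to per-SNP orientation flips", {
  h <- random_instance(10, seed = 99)
  h_flip <- h
  set.seed(17)
  flip <- sample(c(-1, 1), 10, replace = TRUE)
  h_flip$data$beta_exp <- h$data$beta_exp * flip
  h_flip$data$beta_out <- h$data$beta_out * flip
  expect_equal(mr_ivw(h_flip, "random")$beta, mr_ivw(h, "random")$beta)
  expect_equal(mr_egger(h_flip)$beta, mr_egger(h)$beta)
  expect_equal(mr_weighted_median(h_flip, n_boot = 0)$beta,
               mr_weighted_median(h, n_boot = 0)$beta)
  expect_equal(mr_weighted_mode(h_flip, n_boot = 0)$beta,
               mr_weighted_mode(h, n_boot = 0)$beta)
})

test_that("liability scaling multiplies effect and CI by ln(1.5), leaving z alone", {
  plain_estimate <- function(beta, se) {
    tibble::tibble(method = "ivw_random", nsnp = 5L, beta = beta, se = se,
                   ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                   pval = 2 * pnorm(-abs(beta / se)), phi = NA_real_,
                   df = NA_integer_, scale = "per unit exposure")
  }
  est <- plain_estimate(1.0, 0.5)
  scaled <- scale_liability(est, 1.5)
  expect_equal(scaled$beta, log(1.5))
  expect_equal(scaled$se, 0.5 * log(1.5))
  expect_equal(scaled$beta / scaled$se, est$beta / est$se)
  expect_equal(scaled$pval, est$pval)
  expect_match(scaled$scale, "50% higher odds liability")

  # a unit odds factor annihilates the effect
  expect_equal(scale_liability(est, 1)$beta, 0)
  expect_error(scale_liability(est, 0), class = "mrsum_domain_error")

  # z is preserved under any factor and any input
  for (f in c(1.1, 1.5, 2, 5)) {
    e <- plain_estimate(-0.3, 0.12)
    s <- scale_liability(e, f)
    expect_equal(s$beta / s$se, e$beta / e$se)
  }
})
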