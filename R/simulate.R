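#' Configuration for synthetic two-sample summary statistics
#'
#' Describes a two-sample GWAS design with a known causal effect and a chosen
#' horizontal-pleiotropy regime. Per-SNP instrument-exposure effects
#' (`gamma`) are normal; a fraction `prop_invalid` of SNPs receive an
#' additional direct (pleiotropic) outcome effect `alpha`:
#' `"balanced"` draws alpha with mean zero, `"directional"` with mean
#' `mu_alpha` (independent of gamma, so InSIDE holds), and
#' `"directional_inside_violated"` correlates alpha with gamma at `rho`.
#' Standard errors follow the usual GWAS approximation
#' `se = 1 / sqrt(2 maf (1 - maf) n)` for an SD-standardized trait. Because
#' real instruments are discovered at genome-wide significance, true exposure
#' effects are conditioned on detectability (redrawn until the underlying
#' z-statistic clears P < 5e-8), which keeps every simulated instrument as
#' strong as the ones an analyst would actually select.
#'
#' The defaults describe a well-powered modern setting: 100 SNPs, both
#' samples of 100,000, instrument effects averaging 0.08 SD per allele (SD 0.04)
#' (single-SNP F around 150-250), and a causal effect of 0.1.
#'
#' @param n_snps Number of instrument SNPs J.
#' @param theta True causal effect of the exposure on the outcome.
#' @param gamma_mean,gamma_sd Mean and SD of per-SNP exposure effects.
#' @param maf_range Uniform bounds for minor-allele frequency, in (0, 0.5).
#' @param n_exp,n_out Sample sizes of the two GWAS.
#' @param pleiotropy One of `"none"`, `"balanced"`, `"directional"`,
#'   `"directional_inside_violated"`.
#' @param mu_alpha,sigma_alpha Mean and SD of pleiotropic effects on invalid
#'   SNPs.
#' @param rho Correlation between alpha and gamma under the InSIDE-violated
#'   regime.
#' @param prop_invalid Proportion of SNPs receiving pleiotropy.
#' @param exposure_type `"continuous"` or `"binary"` (effects read as log
#'   odds ratios; the generative machinery is shared).
#' @param seed Integer seed; every draw is deterministic given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 100, theta = 0.1,
                       gamma_mean = 0.08, gamma_sd = 0.04,
                       maf_range = c(0.1, 0.4),
                       n_exp = 1e5, n_out = 1e5,
                       pleiotropy = c("none", "balanced", "directional",
                                      "directional_inside_violated"),
                       mu_alpha = 0.02, sigma_alpha = 0.005,
                       rho = 0.7, prop_invalid = 0.3,
                       exposure_type = c("continuous", "binary"),
                       seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  exposure_type <- match.arg(exposure_type)
  stopifnot(n_snps >= 1, prop_invalid >= 0, prop_invalid <= 1,
            abs(rho) <= 1, maf_range[1] > 0, maf_range[2] < 0.5,
            maf_range[1] <= maf_range[2], n_exp > 1, n_out > 1,
            gamma_sd >= 0, sigma_alpha >= 0)
  structure(
    list(n_snps = as.integer(n_snps), theta = theta,
         gamma_mean = gamma_mean, gamma_sd = gamma_sd,
         maf_range = maf_range, n_exp = n_exp, n_out = n_out,
         pleiotropy = pleiotropy, mu_alpha = mu_alpha,
         sigma_alpha = sigma_alpha, rho = rho,
         prop_invalid = prop_invalid, exposure_type = exposure_type,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate two-sample GWAS summary statistics
#'
#' Draws minor-allele frequencies and per-SNP exposure effects, assigns
#' pleiotropic effects according to the configured regime, sets the true
#' outcome effect of each SNP to `theta * gamma + alpha`, and then observes
#' both studies independently: each reported beta is the truth plus normal
#' noise at the standard error implied by allele frequency and sample size.
#' P-values come from the two-sided normal z-test.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `simulated_study`: `exposure` and `outcome`
#'   variant tables (canonical columns), and `truth` (theta plus per-SNP
#'   `gamma`, `alpha`, `maf`, `se_exp`, `se_out`, `invalid`).
#' @export
simulate_summary_stats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  J <- cfg$n_snps
  maf <- runif(J, cfg$maf_range[1], cfg$maf_range[2])
  se_gamma <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exp)
  # instruments are discovered at genome-wide significance, so condition the
  # true effects on detectability: redraw any SNP whose underlying z-statistic
  # could not have cleared P < 5e-8
  z_min <- qnorm(2.5e-8, lower.tail = FALSE)
  gamma <- rnorm(J, cfg$gamma_mean, cfg$gamma_sd)
  for (i in 1:100) {
    weakly <- abs(gamma) / se_gamma < z_min
    if (!any(weakly)) break
    gamma[weakly] <- rnorm(sum(weakly), cfg$gamma_mean, cfg$gamma_sd)
  }
  weakly <- abs(gamma) / se_gamma < z_min
  if (any(weakly)) {  # unreachable threshold for this config: pin at the boundary
    s <- sign(gamma[weakly]); s[s == 0] <- 1
    gamma[weakly] <- s * z_min * se_gamma[weakly]
  }

  n_invalid <- round(cfg$prop_invalid * J)
  invalid <- rep(FALSE, J)
  if (n_invalid > 0) invalid[sample.int(J, n_invalid)] <- TRUE
  alpha <- numeric(J)
  if (n_invalid > 0 && cfg$pleiotropy != "none") {
    e <- rnorm(n_invalid)
    alpha[invalid] <- switch(
      cfg$pleiotropy,
      balanced = cfg$sigma_alpha * e,
      directional = cfg$mu_alpha + cfg$sigma_alpha * e,
      directional_inside_violated = {
        g <- gamma[invalid]
        gstd <- if (sd(g) > 0) (g - mean(g)) / sd(g) else rep(0, n_invalid)
        cfg$mu_alpha + cfg$sigma_alpha * (cfg$rho * gstd + sqrt(1 - cfg$rho^2) * e)
      }
    )
  }
  b_true <- cfg$theta * gamma + alpha

  se_exp <- se_gamma
  se_out <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_out)
  beta_exp <- rnorm(J, gamma, se_exp)
  beta_out <- rnorm(J, b_true, se_out)

  snp <- sprintf("rs%06d", seq_len(J))
  alleles <- cbind(c("A", "C", "G", "T")[sample.int(4, J, replace = TRUE)], "")
  # pick a non-complementary partner so no synthetic SNP is palindromic
  partner <- c(A = "G", C = "T", G = "A", T = "C")
  alleles[, 2] <- partner[alleles[, 1]]

  mk <- function(beta, se, n, trait_type) {
    tibble::tibble(
      snp = snp, chrom = "1",
      pos = as.integer(seq_len(J) * 1e5),
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = maf, beta = beta, se = se,
      pval = z_pval(beta / se), n = as.integer(n),
      trait_type = trait_type
    )
  }
  structure(
    list(exposure = mk(beta_exp, se_exp, cfg$n_exp, cfg$exposure_type),
         outcome = mk(beta_out, se_out, cfg$n_out, "binary"),
         truth = list(theta = cfg$theta, gamma = gamma, alpha = alpha,
                      maf = maf, se_exp = se_exp, se_out = se_out,
                      invalid = invalid),
         config = cfg),
    class = "simulated_study"
  )
}

#' Harmonize a simulated study
#'
#' Convenience wrapper pairing the simulated exposure and outcome tables.
#'
#' @param study A `simulated_study`.
#' @param exposure_label,outcome_label Labels for reports.
#' @return An `mr_harmonized` object.
#' @export
harmonize_simulated <- function(study, exposure_label = "sim_exposure",
                                outcome_label = "sim_outcome") {
  harmonize(study$exposure, study$outcome,
            exposure_label = exposure_label, outcome_label = outcome_label)
}

#' Block-diagonal LD fixture
#'
#' Builds an LD r-squared matrix of `J / block_size` independent blocks with
#' constant within-block r-squared, for exercising clumping rules.
#'
#' @param J Number of SNPs; must be a multiple of `block_size`.
#' @param block_size SNPs per LD block.
#' @param within_block_r2 Off-diagonal r-squared inside each block, in [0, 1].
#' @param snp_ids Optional ids (default `rs000001...`).
#' @return A validated LD matrix.
#' @export
make_ld_fixture <- function(J, block_size, within_block_r2, snp_ids = NULL) {
  if (J %% block_size != 0) {
    abort("block_size must divide J", class = "mrsum_config_error")
  }
  if (within_block_r2 < 0 || within_block_r2 > 1) {
    abort("within_block_r2 must lie in [0, 1]", class = "mrsum_domain_error")
  }
  snp_ids <- snp_ids %||% sprintf("rs%06d", seq_len(J))
  stopifnot(length(snp_ids) == J)
  m <- matrix(0, J, J, dimnames = list(snp_ids, snp_ids))
  for (b in seq_len(J / block_size)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    m[idx, idx] <- within_block_r2
  }
  diag(m) <- 1
  validate_ld_matrix(m)
}

#' Write a simulated study to canonical TSV files
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written (`exposure`, `outcome`, `truth`).
#' @export
write_simulated_study <- function(study, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    exposure = file.path(dir, paste0(prefix, "_exposure.tsv")),
    outcome = file.path(dir, paste0(prefix, "_outcome.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  readr::write_tsv(study$exposure, paths["exposure"])
  readr::write_tsv(study$outcome, paths["outcome"])
  jsonlite::write_json(study$truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
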