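#' Bonferroni evidence tier for one p-value
#'
#' Evidence is `"strong"` when `p < alpha / n_tests` (the Bonferroni-corrected
#' threshold, reported rounded to 4 decimals: 0.05 / 12 = 0.0042),
#' `"suggestive"` when it sits between that threshold and `alpha`, and
#' `"little"` otherwise. A p-value exactly on the corrected threshold is
#' suggestive: the strong tier uses a strict inequality.
#'
#' @param p P-value in (0, 1].
#' @param alpha Nominal significance level (default 0.05).
#' @param n_tests Number of tests corrected for (default 12 risk factors).
#' @return A one-row tibble: `tier`, `threshold_strong`, `alpha`.
#' @export
classify_evidence <- function(p, alpha = 0.05, n_tests = 12) {
  stopifnot(n_tests >= 1)
  if (any(p <= 0 | p > 1)) abort("p must lie in (0, 1]", class = "mrsum_domain_error")
  thr <- round(alpha / n_tests, 4)
  tier <- ifelse(p < thr, "strong", ifelse(p < alpha, "suggestive", "little"))
  tibble::tibble(tier = tier, threshold_strong = thr, alpha = alpha)
}

#' Assemble a declarative analysis configuration
#'
#' @param exposures List of exposure entries: each a list with `label`,
#'   `path` (canonical TSV) or `data` (variant table), `trait_type`,
#'   optional `n` (GWAS sample size), `liability` (logical: rescale to the
#'   liability-odds scale), `trait_sd`, `r2` (externally supplied variance
#'   explained, for binary exposures).
#' @param outcomes List of outcome entries: `label`, `path` or `data`,
#'   optional `n_cases`, `n_controls`.
#' @param alpha,n_tests Evidence-tier thresholds (defaults 0.05 and 12).
#' @param p_instrument,clump_r2,window_kb Instrument-selection thresholds
#'   (defaults 5e-8, 0.001, 10000); clumping runs only when `ld` is supplied
#'   (instrument files are typically pre-clumped).
#' @param f_min Weak-instrument exclusion threshold (default 10).
#' @param palindrome_window Harmonization frequency window (default 0.08).
#' @param liability_odds_factor Odds factor for liability scaling (1.5).
#' @param seed Base seed for all bootstrap draws.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param ld Optional LD matrix enabling a clumping pre-stage.
#' @return An `mr_config` list.
#' @export
mr_config <- function(exposures, outcomes, alpha = 0.05, n_tests = 12,
                      p_instrument = 5e-8, clump_r2 = 0.001, window_kb = 10000,
                      f_min = 10, palindrome_window = 0.08,
                      liability_odds_factor = 1.5, seed = 1L, n_boot = 1000,
                      ld = NULL) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1, n_tests >= 1)
  structure(
    list(exposures = exposures, outcomes = outcomes, alpha = alpha,
         n_tests = n_tests, p_instrument = p_instrument, clump_r2 = clump_r2,
         window_kb = window_kb, f_min = f_min,
         palindrome_window = palindrome_window,
         liability_odds_factor = liability_odds_factor,
         seed = as.integer(seed), n_boot = n_boot, ld = ld),
    class = "mr_config"
  )
}

#' Read an analysis configuration from YAML or JSON
#'
#' The file holds the fields of [mr_config()]; exposure/outcome entries name
#' their summary-statistic files by path (resolved relative to the config
#' file).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `mr_config` list.
#' @export
read_mr_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path), class = "mrsum_io_error")
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  base <- dirname(path)
  fix_paths <- function(entries) lapply(entries, function(e) {
    if (!is.null(e$path) && !file.exists(e$path)) e$path <- file.path(base, e$path)
    e
  })
  args <- raw
  args$exposures <- fix_paths(raw$exposures)
  args$outcomes <- fix_paths(raw$outcomes)
  do.call(mr_config, args)
}

load_variants <- function(entry, role) {
  tt <- entry$trait_type %||% "continuous"
  if (!is.null(entry$data)) return(as_sumstats(entry$data, trait_type = tt,
                                               source = entry$label %||% role))
  if (is.null(entry$path)) {
    abort(paste0(role, " entry '", entry$label %||% "?", "' has neither data nor path"),
          class = "mrsum_config_error")
  }
  read_sumstats(entry$path, dialect = entry$dialect, trait_type = tt)
}

# format one estimate for a printed table: "OR (lo-hi)" at 2 decimals
format_or_ci <- function(beta, ci_low, ci_high) {
  sprintf("%.2f (%.2f-%.2f)", exp(beta), exp(ci_low), exp(ci_high))
}

UNAVAILABLE_MARK <- "—"  # em dash, as in printed tables

#' Run the full risk-factor-by-outcome MR analysis grid
#'
#' For every exposure-outcome pair: (optional) LD clumping of the exposure
#' instrument, allele harmonization, instrument-strength gating (F >= 10 when
#' computable), the estimator suite under the method-availability rules (IVW
#' auto fixed/random; Egger and weighted median from 3 SNPs; weighted mode
#' from 5), liability scaling of binary exposures flagged `liability`,
#' Cochran's Q, leave-one-out, Steiger directionality, and a Bonferroni
#' evidence tier on the IVW p-value. Given the same config (including seed)
#' the output is fully deterministic.
#'
#' @param config An [mr_config()].
#' @return A list of class `mr_report`: `master` (one row per pair and
#'   method, long format), `tables` (one wide, printed-style table per
#'   outcome with unavailable methods marked by an em dash), `sensitivity`
#'   (Q, Steiger, leave-one-out range per pair), `excluded` (pairs excluded
#'   with reasons), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  master <- list(); sens <- list(); excluded <- list(); loo_tabs <- list()

  for (ex in config$exposures) {
    ex_label <- ex$label %||% "exposure"
    variants <- load_variants(ex, "exposure")
    if (!is.null(config$ld)) {
      kept <- clump(variants, config$ld, r2_threshold = config$clump_r2,
                    window_kb = config$window_kb, p_threshold = config$p_instrument)
      variants <- variants[variants$snp %in% kept, , drop = FALSE]
    }
    if (!nrow(variants)) {
      excluded[[length(excluded) + 1]] <- tibble::tibble(
        exposure = ex_label, outcome = NA_character_,
        reason = "no instrument SNPs after selection")
      next
    }

    # instrument strength: from eaf/beta when possible, else caller-supplied r2
    strength <- NULL
    r2 <- ex$r2
    if (is.null(r2) && !anyNA(variants$eaf) && !is.null(ex$n)) {
      r2 <- variance_explained(variants, trait_sd = ex$trait_sd %||% 1)
    }
    if (!is.null(r2) && !is.null(ex$n)) {
      f <- f_statistic(r2, ex$n, nrow(variants))
      strength <- tibble::tibble(r2_total = r2, f_stat = f,
                                 n_snps = nrow(variants), n_sample = ex$n)
      if (!weak_instrument_gate(f, config$f_min)) {
        excluded[[length(excluded) + 1]] <- tibble::tibble(
          exposure = ex_label, outcome = NA_character_,
          reason = sprintf("weak instrument (F = %.1f < %.0f)", f, config$f_min))
        inform(sprintf("excluding '%s': F = %.1f below %.0f", ex_label, f, config$f_min))
        next
      }
    }

    for (ou in config$outcomes) {
      ou_label <- ou$label %||% "outcome"
      outcome <- load_variants(ou, "outcome")
      h <- harmonize(variants, outcome,
                     palindrome_eaf_window = config$palindrome_window,
                     exposure_label = ex_label, outcome_label = ou_label)
      pair_seed <- child_seed(config$seed, paste(ex_label, ou_label))
      est <- mr_all(h, n_boot = config$n_boot, seed = pair_seed)

      liability <- isTRUE(ex$liability)
      if (liability) est <- scale_liability(est, config$liability_odds_factor)
      else est$scale <- ex$scale %||% est$scale

      ivw_row <- est[grepl("^ivw|^wald", est$method), ][1, ]
      tier <- classify_evidence(ivw_row$pval, config$alpha, config$n_tests)

      q <- if (n_snps(h) >= 2) cochran_q(h) else
        tibble::tibble(Q = NA_real_, df = NA_integer_, pval = NA_real_, phi = NA_real_)
      st <- tryCatch(steiger(h)$global, error = function(e)
        tibble::tibble(snp = "global", r2_exposure = NA_real_, r2_outcome = NA_real_,
                       direction_exposure_to_outcome = NA, steiger_p = NA_real_))
      loo_rng <- c(NA_real_, NA_real_)
      if (n_snps(h) >= 3) {
        loo <- leave_one_out(h)
        loo_rng <- range(loo$loo$beta)
        loo_tabs[[paste(ex_label, ou_label, sep = " -> ")]] <- loo$loo
      }

      master[[length(master) + 1]] <- dplyr::bind_cols(
        tibble::tibble(exposure = ex_label, outcome = ou_label), est,
        tibble::tibble(ivw_tier = tier$tier,
                       f_stat = strength$f_stat %||% NA_real_,
                       n_kept = n_snps(h), n_dropped = nrow(h$audit)))
      sens[[length(sens) + 1]] <- tibble::tibble(
        exposure = ex_label, outcome = ou_label,
        Q = q$Q, Q_df = q$df, Q_pval = q$pval, phi = q$phi,
        steiger_direction = st$direction_exposure_to_outcome,
        steiger_p = st$steiger_p,
        loo_beta_min = loo_rng[1], loo_beta_max = loo_rng[2])
    }
  }

  master <- dplyr::bind_rows(master)
  if (!nrow(master)) abort("no analyses completed", class = "mrsum_analysis_error")
  structure(
    list(master = master,
         tables = build_outcome_tables(master),
         sensitivity = dplyr::bind_rows(sens),
         leave_one_out = loo_tabs,
         excluded = dplyr::bind_rows(excluded),
         config = config),
    class = "mr_report"
  )
}

# one printed-style wide table per outcome; methods an exposure lacks get an
# explicit dash, never an omitted cell
build_outcome_tables <- function(master) {
  methods <- c(ivw = "^(ivw_fixed|ivw_random|wald_single)$",
               egger = "^egger_slope$", egger_intercept = "^egger_intercept$",
               weighted_median = "^weighted_median$", weighted_mode = "^weighted_mode$")
  split_out <- split(master, master$outcome)
  lapply(split_out, function(tab) {
    rows <- lapply(split(tab, factor(tab$exposure, unique(tab$exposure))), function(g) {
      row <- tibble::tibble(risk_factor = g$exposure[1], n_snps = max(g$nsnp))
      for (m in names(methods)) {
        hit <- g[grepl(methods[m], g$method), ]
        if (nrow(hit) == 1 && !is.na(hit$se)) {
          row[[paste0(m, "_or_ci")]] <- format_or_ci(hit$beta, hit$ci_low, hit$ci_high)
          row[[paste0(m, "_pval")]] <- format(signif(hit$pval, 2), scientific = hit$pval < 1e-3)
        } else {
          row[[paste0(m, "_or_ci")]] <- UNAVAILABLE_MARK
          row[[paste0(m, "_pval")]] <- UNAVAILABLE_MARK
        }
      }
      row$evidence <- g$ivw_tier[1]
      row
    })
    dplyr::bind_rows(rows)
  })
}

#' Write an analysis report to disk
#'
#' Emits the long-format master TSV, one printed-style TSV per outcome, the
#' sensitivity TSV, leave-one-out TSVs and the exclusion log. Output is
#' byte-identical across runs with the same config and seed.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if needed).
#' @param plots Also write forest/scatter plots as PNG (default `FALSE`).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, plots = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  slug <- function(x) gsub("[^A-Za-z0-9._-]+", "_", tolower(x))

  p <- file.path(dir, "master.tsv")
  readr::write_tsv(report$master, p); paths <- c(paths, p)
  p <- file.path(dir, "sensitivity.tsv")
  readr::write_tsv(report$sensitivity, p); paths <- c(paths, p)
  if (nrow(report$excluded)) {
    p <- file.path(dir, "excluded.tsv")
    readr::write_tsv(report$excluded, p); paths <- c(paths, p)
  }
  for (ou in names(report$tables)) {
    p <- file.path(dir, paste0("table_", slug(ou), ".tsv"))
    readr::write_tsv(report$tables[[ou]], p); paths <- c(paths, p)
  }
  for (pair in names(report$leave_one_out)) {
    p <- file.path(dir, paste0("loo_", slug(pair), ".tsv"))
    readr::write_tsv(report$leave_one_out[[pair]], p); paths <- c(paths, p)
  }
  if (plots) {
    for (ou in names(report$tables)) {
      est <- report$master[report$master$outcome == ou &
                             grepl("^(ivw|wald)", report$master$method), ]
      p <- file.path(dir, paste0("forest_", slug(ou), ".png"))
      ggplot2::ggsave(p, forest_plot(est), width = 7, height = 1 + 0.5 * nrow(est),
                      dpi = 150)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
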