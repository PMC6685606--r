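#' Align exposure and outcome summary statistics to a shared effect allele
#'
#' For every SNP present in both studies, the outcome association is expressed
#' per copy of the exposure's effect allele. Swapped alleles flip the sign of
#' the outcome beta (and reflect its allele frequency); strand flips are
#' resolved by complementing the outcome alleles before comparison.
#' Palindromic SNPs (A/T or C/G), whose strand cannot be inferred from alleles
#' alone, are oriented by allele frequency and kept only when both frequencies
#' are available and both sit outside `0.5 +/- palindrome_eaf_window`;
#' otherwise they are dropped with the action recorded. SNPs whose alleles
#' cannot be reconciled under either strand are dropped as incompatible.
#'
#' @param exposure,outcome Variant tables from [read_sumstats()] /
#'   [as_sumstats()].
#' @param palindrome_eaf_window Half-width of the ambiguous frequency zone
#'   around 0.5 within which a palindromic SNP is dropped (default 0.08).
#' @param exposure_label,outcome_label Trait labels carried into reports.
#' @return An object of class `mr_harmonized`: a list with `data` (kept
#'   records: `snp`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`,
#'   `eaf_out`, `pval_exp`, `pval_out`, `palindromic`, `action`), `audit`
#'   (dropped records with the reason), the labels and the exposure trait
#'   type.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                      exposure_label = "exposure", outcome_label = "outcome") {
  stopifnot(palindrome_eaf_window >= 0, palindrome_eaf_window < 0.5)
  if (anyDuplicated(exposure$snp)) abort("duplicate snp ids in exposure", class = "mrsum_validation_error")
  if (anyDuplicated(outcome$snp)) abort("duplicate snp ids in outcome", class = "mrsum_validation_error")

  shared <- intersect(exposure$snp, outcome$snp)
  if (!length(shared)) {
    abort(paste0("no shared SNPs between '", exposure_label, "' and '", outcome_label, "'"),
          class = "mrsum_analysis_error")
  }
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]

  n <- length(shared)
  action <- character(n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  palin <- is_palindromic(ex$effect_allele, ex$other_allele)

  for (i in seq_len(n)) {
    ea_e <- ex$effect_allele[i]; oa_e <- ex$other_allele[i]
    ea_o <- ou$effect_allele[i]; oa_o <- ou$other_allele[i]

    if (palin[i]) {
      # letters cannot distinguish a strand flip from an allele swap; use EAF
      letters_ok <- setequal(c(ea_o, oa_o), c(ea_e, oa_e))
      if (!letters_ok) { action[i] <- "dropped_incompatible"; next }
      e_eaf <- ex$eaf[i]; o_eaf <- ou$eaf[i]
      if (ea_o != ea_e) {            # letter-wise swap: orient to exposure allele
        beta_out[i] <- -beta_out[i]
        if (!is.na(o_eaf)) o_eaf <- 1 - o_eaf
      }
      ambiguous <- is.na(e_eaf) || is.na(o_eaf) ||
        abs(e_eaf - 0.5) <= palindrome_eaf_window ||
        abs(o_eaf - 0.5) <= palindrome_eaf_window
      if (ambiguous) { action[i] <- "dropped_palindromic"; next }
      if (sign(e_eaf - 0.5) != sign(o_eaf - 0.5)) {  # opposite strand: flip again
        beta_out[i] <- -beta_out[i]
        o_eaf <- 1 - o_eaf
      }
      eaf_out[i] <- o_eaf
      action[i] <- if (identical(beta_out[i], ou$beta[i])) "kept_as_is" else "flipped_outcome"
      next
    }

    if (ea_o == ea_e && oa_o == oa_e) {
      action[i] <- "kept_as_is"
    } else if (ea_o == oa_e && oa_o == ea_e) {
      action[i] <- "flipped_outcome"
    } else {
      ea_c <- complement_allele(ea_o); oa_c <- complement_allele(oa_o)
      if (ea_c == ea_e && oa_c == oa_e) {
        action[i] <- "kept_as_is"
      } else if (ea_c == oa_e && oa_c == ea_e) {
        action[i] <- "flipped_outcome"
      } else {
        action[i] <- "dropped_incompatible"
        next
      }
    }
    if (action[i] == "flipped_outcome") {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
    }
  }

  rec <- tibble::tibble(
    snp = shared,
    beta_exp = ex$beta, se_exp = ex$se,
    beta_out = beta_out, se_out = ou$se,
    eaf_exp = ex$eaf, eaf_out = eaf_out,
    pval_exp = ex$pval, pval_out = ou$pval,
    n_exp = ex$n, n_out = ou$n,
    chrom = ex$chrom, pos = ex$pos,
    palindromic = palin,
    action = action
  )
  kept <- rec[rec$action %in% c("kept_as_is", "flipped_outcome"), , drop = FALSE]
  audit <- rec[!rec$action %in% c("kept_as_is", "flipped_outcome"), , drop = FALSE]
  if (!nrow(kept)) {
    warn(paste0("harmonization of '", exposure_label, "' vs '", outcome_label,
                "' left no usable SNPs (all dropped; see audit)"))
  }
  structure(
    list(exposure_label = exposure_label, outcome_label = outcome_label,
         exposure_trait_type = exposure$trait_type[1] %||% "continuous",
         data = kept, audit = audit),
    class = "mr_harmonized"
  )
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat("Harmonized two-sample MR dataset: ", x$exposure_label, " -> ",
      x$outcome_label, "\n", sep = "")
  cat("  ", nrow(x$data), " SNP(s) kept, ", nrow(x$audit), " dropped (",
      x$exposure_trait_type, " exposure)\n", sep = "")
  invisible(x)
}

#' Number of SNPs in a harmonized dataset
#' @param x An `mr_harmonized` object.
#' @return Integer SNP count.
#' @export
n_snps <- function(x) nrow(x$data)
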