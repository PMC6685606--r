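#' Read a pairwise LD matrix from a square TSV
#'
#' The expected layout is a square tab-separated table whose header row and
#' first column both hold SNP ids, with pairwise LD r-squared values in the
#' body.
#'
#' @param path Path to the TSV.
#' @return A validated symmetric matrix with unit diagonal (see
#'   [validate_ld_matrix()]).
#' @export
read_ld_matrix <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  validate_ld_matrix(m)
}

#' Validate an LD r-squared matrix
#'
#' @param m Square numeric matrix with SNP ids as dimnames.
#' @param tol Numerical tolerance for symmetry and the unit diagonal.
#' @return `m`, invisibly validated (dimnames aligned).
#' @export
validate_ld_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("LD matrix must be square", class = "mrsum_validation_error")
  }
  if (is.null(rownames(m)) && is.null(colnames(m))) {
    abort("LD matrix needs SNP ids as dimnames", class = "mrsum_validation_error")
  }
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (anyDuplicated(rownames(m))) abort("duplicate SNP ids in LD matrix", class = "mrsum_validation_error")
  if (!identical(rownames(m), colnames(m))) {
    abort("LD matrix row and column ids disagree", class = "mrsum_validation_error")
  }
  if (max(abs(m - t(m))) > tol) {
    abort("LD matrix is not symmetric", class = "mrsum_validation_error")
  }
  if (max(abs(diag(m) - 1)) > tol) {
    abort("LD matrix diagonal must be 1", class = "mrsum_validation_error")
  }
  if (min(m) < -tol || max(m) > 1 + tol) {
    abort("LD r-squared values must lie in [0, 1]", class = "mrsum_validation_error")
  }
  m
}

#' Greedy LD clumping of genome-wide-significant variants
#'
#' Variants at or below `p_threshold` are ranked by ascending p-value (ties
#' broken by snp id for determinism) and kept greedily: a candidate is
#' discarded when it lies within `window_kb` of an already-kept SNP (missing
#' positions count as within the window, so LD alone decides) *and* its LD
#' r-squared with that SNP exceeds `r2_threshold`. Pairs absent from the LD
#' matrix are treated as unlinked.
#'
#' @param variants Variant table (needs `snp`, `pval`; `chrom`/`pos` optional).
#' @param ld LD r-squared matrix (see [validate_ld_matrix()]); `NULL` means no
#'   LD information, i.e. all pairs unlinked.
#' @param r2_threshold LD r-squared above which two SNPs are dependent
#'   (default 0.001).
#' @param window_kb Clumping distance in kilobases (default 10000).
#' @param p_threshold Genome-wide significance cut-off (default 5e-8).
#' @return Character vector of kept snp ids, ordered by p-value.
#' @export
clump <- function(variants, ld = NULL, r2_threshold = 0.001,
                  window_kb = 10000, p_threshold = 5e-8) {
  if (!is.null(ld)) ld <- validate_ld_matrix(ld)
  v <- variants[!is.na(variants$pval) & variants$pval <= p_threshold, , drop = FALSE]
  if (!nrow(v)) return(character(0))
  v <- v[order(v$pval, v$snp), , drop = FALSE]

  has_pos <- !is.null(v$pos) && !is.null(v$chrom)
  r2_of <- function(a, b) {
    if (is.null(ld) || !(a %in% rownames(ld)) || !(b %in% rownames(ld))) return(0)
    ld[a, b]
  }
  in_window <- function(i, j) {
    if (!has_pos) return(TRUE)
    ci <- v$chrom[i]; cj <- v$chrom[j]; pi <- v$pos[i]; pj <- v$pos[j]
    if (is.na(ci) || is.na(cj) || is.na(pi) || is.na(pj)) return(TRUE)
    ci == cj && abs(pi - pj) <= window_kb * 1000
  }

  kept <- integer(0)
  for (i in seq_len(nrow(v))) {
    excluded <- FALSE
    for (j in kept) {
      if (in_window(i, j) && r2_of(v$snp[i], v$snp[j]) > r2_threshold) {
        excluded <- TRUE
        break
      }
    }
    if (!excluded) kept <- c(kept, i)
  }
  v$snp[kept]
}

#' Variance in the exposure explained by an instrument
#'
#' Under Hardy-Weinberg equilibrium each biallelic SNP with effect-allele
#' frequency `p` and per-allele effect `beta` explains
#' `2 p (1 - p) beta^2 / sd^2` of the trait variance; the instrument total is
#' the sum over its (independent) SNPs, clamped to `[0, 1]` with a warning
#' when the clamp bites.
#'
#' @param variants Variant table or harmonized exposure effects with `eaf`
#'   (or `eaf_exp`) and `beta` (or `beta_exp`).
#' @param trait_sd Standard deviation of the exposure in its analysis units
#'   (1 for SD-standardized traits).
#' @return The total r-squared, a proportion.
#' @export
variance_explained <- function(variants, trait_sd = 1) {
  stopifnot(trait_sd > 0)
  eaf <- variants$eaf %||% variants$eaf_exp
  beta <- variants$beta %||% variants$beta_exp
  if (is.null(eaf) || is.null(beta)) {
    abort("variance_explained needs eaf and beta columns", class = "mrsum_analysis_error")
  }
  if (anyNA(eaf)) {
    miss <- variants$snp[is.na(eaf)]
    abort(paste0("missing eaf for SNP(s): ", paste(miss, collapse = ", ")),
          class = "mrsum_analysis_error")
  }
  r2 <- sum(2 * eaf * (1 - eaf) * beta^2) / trait_sd^2
  if (r2 > 1) {
    warn(sprintf("instrument r-squared %.3f exceeds 1; clamped (check trait_sd)", r2))
    r2 <- 1
  }
  r2
}

#' Instrument F-statistic
#'
#' `F = (R2 / (1 - R2)) * ((n - k - 1) / k)` for an instrument of `k` SNPs
#' jointly explaining `R2` of the exposure variance in a GWAS of `n` samples.
#' F below 10 conventionally flags weak-instrument bias risk.
#'
#' @param r2_total Proportion of variance explained, in `[0, 1)`.
#' @param n_sample GWAS sample size (must exceed `n_snps + 1`).
#' @param n_snps Number of SNPs in the instrument.
#' @return The F-statistic.
#' @export
f_statistic <- function(r2_total, n_sample, n_snps) {
  if (any(r2_total < 0) || any(r2_total >= 1)) {
    abort("r2_total must lie in [0, 1)", class = "mrsum_domain_error")
  }
  stopifnot(n_sample > n_snps + 1, n_snps >= 1)
  (r2_total / (1 - r2_total)) * ((n_sample - n_snps - 1) / n_snps)
}

#' Weak-instrument inclusion gate
#'
#' @param f_stat Instrument F-statistic.
#' @param f_min Minimum F for inclusion (default 10).
#' @return `TRUE` when the instrument is strong enough to analyse.
#' @export
weak_instrument_gate <- function(f_stat, f_min = 10) {
  stopifnot(f_stat >= 0)
  f_stat >= f_min
}

#' Summarise instrument strength
#'
#' @param variants Exposure variant table with `eaf` and `beta`.
#' @param n_sample Exposure GWAS sample size.
#' @param trait_sd Exposure standard deviation (default 1).
#' @return A one-row tibble: `r2_total`, `f_stat`, `n_snps`, `n_sample`,
#'   `include` (the F >= 10 gate).
#' @export
instrument_strength <- function(variants, n_sample, trait_sd = 1) {
  r2 <- variance_explained(variants, trait_sd = trait_sd)
  k <- nrow(variants)
  f <- f_statistic(r2, n_sample, k)
  tibble::tibble(r2_total = r2, f_stat = f, n_snps = k, n_sample = n_sample,
                 include = weak_instrument_gate(f))
}
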