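#' Canonical summary-statistic column names
#'
#' The canonical dialect is a tab-separated table with one header row and
#' lower-case column names: `snp`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. Only `snp`,
#' `effect_allele`, `other_allele`, `beta` and `se` are mandatory; effect
#' sizes for binary traits are natural-log odds ratios.
#'
#' @return Character vector of canonical column names.
#' @export
canonical_columns <- function() {
  c("snp", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pval", "n")
}

mandatory_columns <- function() c("snp", "effect_allele", "other_allele", "beta", "se")

#' Read GWAS summary statistics into a validated variant table
#'
#' Reads a delimited file of per-SNP association statistics and validates each
#' row against the variant-association contract: ACGT alleles that differ,
#' positive standard errors, allele frequencies strictly inside (0, 1) and
#' p-values in (0, 1]. Malformed rows are collected with their line numbers
#' and reported; they are never silently dropped.
#'
#' @param path Path to a delimited text file with one header row.
#' @param dialect Named character vector mapping canonical column names to the
#'   file's column names, e.g. `c(snp = "rsid", beta = "b")`. Columns not
#'   mentioned are looked up under their canonical names.
#' @param trait_type `"continuous"` or `"binary"` (betas are log odds ratios).
#' @param delim Field delimiter, tab by default.
#' @param on_invalid `"error"` (default) aborts listing the offending lines;
#'   `"warn"` drops them with a warning naming each line.
#' @return A tibble with canonical columns plus `trait_type`.
#' @export
read_sumstats <- function(path, dialect = NULL,
                          trait_type = c("continuous", "binary"),
                          delim = "\t",
                          on_invalid = c("error", "warn")) {
  trait_type <- match.arg(trait_type)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) {
    abort(paste0("summary-statistics file not found: ", path), class = "mrsum_io_error")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  as_sumstats(raw, dialect = dialect, trait_type = trait_type,
              on_invalid = on_invalid, source = path)
}

#' Coerce a data frame to a validated variant table
#'
#' @inheritParams read_sumstats
#' @param x Data frame holding one row per variant.
#' @param source Label used in error messages.
#' @return A tibble with canonical columns plus `trait_type`.
#' @export
as_sumstats <- function(x, dialect = NULL,
                        trait_type = c("continuous", "binary"),
                        on_invalid = c("error", "warn"),
                        source = "input") {
  trait_type <- match.arg(trait_type)
  on_invalid <- match.arg(on_invalid)
  x <- tibble::as_tibble(x)

  lookup <- setNames(canonical_columns(), canonical_columns())
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), canonical_columns())
    if (length(bad)) {
      abort(paste0("unknown canonical names in dialect: ", paste(bad, collapse = ", ")),
            class = "mrsum_config_error")
    }
    lookup[names(dialect)] <- unname(dialect)
  }
  missing_cols <- mandatory_columns()[!lookup[mandatory_columns()] %in% names(x)]
  if (length(missing_cols)) {
    abort(paste0("missing mandatory column(s) in ", source, ": ",
                 paste(lookup[missing_cols], collapse = ", "),
                 " (canonical: ", paste(missing_cols, collapse = ", "), ")"),
          class = "mrsum_config_error")
  }

  out <- tibble::tibble(.line = seq_len(nrow(x)) + 1L)  # +1 for header line
  for (canon in canonical_columns()) {
    col <- lookup[[canon]]
    out[[canon]] <- if (col %in% names(x)) x[[col]] else NA
  }
  out$snp <- as.character(out$snp)
  out$chrom <- as.character(out$chrom)
  out$effect_allele <- toupper(as.character(out$effect_allele))
  out$other_allele <- toupper(as.character(out$other_allele))
  for (num in c("pos", "eaf", "beta", "se", "pval", "n")) {
    out[[num]] <- suppressWarnings(as.numeric(out[[num]]))
  }
  out$pos <- as.integer(round(out$pos))
  out$n <- as.integer(round(out$n))

  problems <- character(0)
  flag <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx)) {
      problems <<- c(problems,
                     paste0("line ", out$.line[idx], " (", out$snp[idx], "): ", msg))
    }
    cond
  }
  bad <- flag(is.na(out$snp) | out$snp == "", "missing snp id")
  bad <- bad | flag(!is_acgt(out$effect_allele), "effect allele not one of A/C/G/T")
  bad <- bad | flag(!is_acgt(out$other_allele), "other allele not one of A/C/G/T")
  bad <- bad | flag(is_acgt(out$effect_allele) & is_acgt(out$other_allele) &
                      out$effect_allele == out$other_allele,
                    "effect and other allele identical")
  bad <- bad | flag(is.na(out$beta), "missing or non-numeric beta")
  bad <- bad | flag(is.na(out$se) | out$se <= 0, "se missing or not > 0")
  bad <- bad | flag(!is.na(out$eaf) & (out$eaf <= 0 | out$eaf >= 1),
                    "eaf outside (0, 1)")
  bad <- bad | flag(!is.na(out$pval) & (out$pval <= 0 | out$pval > 1),
                    "pval outside (0, 1]")

  if (any(bad)) {
    msg <- paste0(sum(bad), " invalid row(s) in ", source, ":\n  ",
                  paste(head(problems, 20), collapse = "\n  "))
    if (on_invalid == "error") abort(msg, class = "mrsum_validation_error")
    warn(msg)
    out <- out[!bad, , drop = FALSE]
  }
  if (!nrow(out)) abort(paste0("no valid rows in ", source), class = "mrsum_validation_error")

  # published tables round aggressively, so p/beta coherence is advisory only
  with_p <- !is.na(out$pval) & !is.na(out$beta) & !is.na(out$se)
  if (any(with_p)) {
    implied <- z_pval(out$beta[with_p] / out$se[with_p])
    ratio <- out$pval[with_p] / implied
    off <- with_p
    off[with_p] <- ratio > 10 | ratio < 0.1
    if (any(off, na.rm = TRUE)) {
      warn(paste0("pval disagrees with |beta/se| by >10x for ",
                  sum(off, na.rm = TRUE), " row(s) in ", source,
                  " (e.g. ", out$snp[which(off)[1]], ")"))
    }
  }

  out$trait_type <- trait_type
  out$.line <- NULL
  out
}

#' Convert an XLSX workbook of summary statistics to canonical TSV files
#'
#' Each sheet becomes one tab-separated file named `<stem>__<sheet>.tsv` in
#' `out_dir`, written with a stable row and column order so the conversion is
#' reproducible byte for byte. Values are written as-is; validation happens
#' later in [read_sumstats()].
#'
#' @param path Path to an `.xlsx` workbook.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths of the TSV files written (named by sheet).
#' @export
convert_xlsx <- function(path, out_dir = dirname(path)) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    abort("the readxl package is required to read XLSX workbooks",
          class = "mrsum_config_error")
  }
  if (!file.exists(path)) abort(paste0("workbook not found: ", path), class = "mrsum_io_error")
  sheets <- tryCatch(readxl::excel_sheets(path),
                     error = function(e) abort(paste0("unreadable workbook: ", path,
                                                      " (", conditionMessage(e), ")"),
                                               class = "mrsum_io_error"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sub("\\.[^.]+$", "", basename(path))
  out <- character(0)
  for (sheet in sheets) {
    tab <- readxl::read_excel(path, sheet = sheet, col_types = "text")
    safe <- gsub("[^A-Za-z0-9._-]+", "_", sheet)
    dest <- file.path(out_dir, paste0(stem, "__", safe, ".tsv"))
    readr::write_tsv(tab, dest, na = "")
    out[sheet] <- dest
  }
  invisible(out)
}
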