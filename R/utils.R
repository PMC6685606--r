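#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats pnorm qnorm pt qt pchisq rnorm runif sd mad median setNames
#' @importFrom utils head
NULL

# two-sided normal p-value, never exactly 0 in reports
z_pval <- function(z) {
  p <- 2 * pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

# two-sided t p-value
t_pval <- function(t, df) {
  p <- 2 * pt(-abs(t), df = df)
  pmax(p, .Machine$double.xmin)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) unname(DNA_COMPLEMENT[toupper(x)])

is_palindromic <- function(ea, oa) complement_allele(ea) == toupper(oa)

is_acgt <- function(x) toupper(x) %in% c("A", "C", "G", "T")

# derive a reproducible, 32-bit-safe child seed from a base seed and a label
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) + (h %% 1000003L)) %% .Machine$integer.max
}
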