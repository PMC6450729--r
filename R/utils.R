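#' @keywords internal
"_PACKAGE"

## numerically safe log-space accumulation ---------------------------------

#' Log-sum-exp of a numeric vector
#'
#' Computes `log(sum(exp(x)))` without overflow; needed because approximate
#' Bayes factors at z ~ 40 reach exp(800).
#'
#' @param x numeric vector (may contain -Inf).
#' @return scalar, `log(sum(exp(x)))`.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a >= b; returns -Inf when a ~ b
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

## allele helpers -----------------------------------------------------------

ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Strand complement of allele strings
#'
#' Single-base alleles are complemented; indel strings are returned verbatim
#' (strand flips are not resolvable for indels and they are never
#' palindromic in the SNP sense).
#'
#' @param a character vector of alleles (upper case).
#' @return complemented alleles.
#' @keywords internal
complement_alleles <- function(a) {
  out <- ALLELE_COMPLEMENT[a]
  out[is.na(out)] <- a[is.na(out)]
  unname(out)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

## seeding ------------------------------------------------------------------

#' Derive a deterministic sub-seed
#'
#' All generators draw from sub-streams derived from one named master seed,
#' so that adding a simulation stage never perturbs the draws of another.
#' Kept below 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed master integer seed.
#' @param stream integer stream index (>= 1).
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 1103 * stream) %% 2147483629L)
}

## two-sided p-values -------------------------------------------------------

pval_norm <- function(z) 2 * stats::pnorm(-abs(z))
pval_t <- function(tstat, df) 2 * stats::pt(-abs(tstat), df = df)

## odds-ratio formatting used in result rows
or_ci <- function(beta, se, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(beta), lo = exp(beta - zq * se), hi = exp(beta + zq * se))
}
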