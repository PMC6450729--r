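## Bayesian colocalization of two traits in one genomic region via
## Wakefield approximate Bayes factors, under the single-causal-variant
## assumption. All accumulation happens in log space (log-sum-exp) so that
## panels with z around 40 remain finite.

#' Wakefield approximate Bayes factor (log scale)
#'
#' With `z = beta/se`, `V = se^2`, `W = prior_sd^2` and shrinkage
#' `r = W / (V + W)`: `log ABF = 0.5 log(1 - r) + 0.5 z^2 r`, the evidence
#' for association against the point null under a N(0, W) effect prior.
#'
#' @param beta,se effect and standard error (se > 0); vectorized.
#' @param prior_sd prior standard deviation of the true effect; the
#'   conventional defaults are 0.20 for binary traits (log-odds scale) and
#'   0.15 for quantitative traits.
#' @return log approximate Bayes factor(s).
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.2) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  z <- beta / se
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Region panel for colocalization
#'
#' Per-variant association summaries for two traits across one region
#' (conventionally the instrument +/- 1 Mb).
#'
#' @param region_id label.
#' @param variant_id character vector.
#' @param beta1,se1,beta2,se2 per-variant effects/SEs for traits 1 and 2.
#' @param chrom,start,end region coordinates (start < end).
#' @param type1,type2 `"binary"` or `"quantitative"` (sets the ABF prior
#'   sd per trait).
#' @return object of class `region_panel`.
#' @export
region_panel <- function(region_id, variant_id, beta1, se1, beta2, se2,
                         chrom = NA_character_, start = NA_integer_,
                         end = NA_integer_,
                         type1 = "binary", type2 = "binary") {
  k <- length(variant_id)
  stopifnot(length(beta1) == k, length(se1) == k,
            length(beta2) == k, length(se2) == k,
            all(se1 > 0), all(se2 > 0))
  if (!is.na(start) && !is.na(end) && start >= end) stop("start must be < end")
  structure(list(region_id = region_id, variant_id = as.character(variant_id),
                 beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                 chrom = chrom, start = start, end = end,
                 type1 = type1, type2 = type2),
            class = "region_panel")
}

prior_sd_for <- function(type) if (type == "quantitative") 0.15 else 0.20

#' Colocalization posterior probabilities for one region
#'
#' Computes per-variant Wakefield log-ABFs for each trait and the posterior
#' probabilities of the five hypotheses: H0 no association, H1/H2 one
#' trait only, H3 two distinct causal variants, H4 one shared causal
#' variant. Unnormalized hypothesis masses are
#' `H0: 1`, `H1: p1 sum BF1`, `H2: p2 sum BF2`,
#' `H3: p1 p2 (sum BF1 sum BF2 - sum BF1 BF2)`, `H4: p12 sum BF1 BF2`,
#' normalized in log space. The per-variant H4 posterior is proportional
#' to `BF1_i * BF2_i`. A region with `PPH4 > 0.95` is flagged as strong
#' evidence of colocalization.
#'
#' @param panel a [region_panel].
#' @param p1,p2 prior probabilities a variant is causal for trait 1 / 2
#'   only (defaults 1e-4).
#' @param p12 prior probability a variant is causal for both (default 1e-5).
#' @param prior_sd1,prior_sd2 ABF prior sds; default set by trait type.
#' @return object of class `coloc_result`: `pph` (named numeric, H0..H4,
#'   sums to 1), `h4_posterior` (per-variant, sums to 1), `top_variant`,
#'   `top_variant_h4`, `colocalized` (PPH4 > 0.95), `n_variants`.
#'   A single-variant panel cannot support H3; it is reported as 0 with a
#'   warning.
#' @export
coloc_region <- function(panel, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd1 = prior_sd_for(panel$type1),
                         prior_sd2 = prior_sd_for(panel$type2)) {
  k <- length(panel$variant_id)
  labf1 <- wakefield_abf(panel$beta1, panel$se1, prior_sd1)
  labf2 <- wakefield_abf(panel$beta2, panel$se2, prior_sd2)

  ls1 <- logsumexp(labf1)            # log sum_i BF1_i
  ls2 <- logsumexp(labf2)
  ls12 <- logsumexp(labf1 + labf2)   # log sum_i BF1_i BF2_i

  lh <- c(
    H0 = 0,
    H1 = log(p1) + ls1,
    H2 = log(p2) + ls2,
    H3 = if (k >= 2) log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls12) else -Inf,
    H4 = log(p12) + ls12
  )
  if (k < 2) {
    warning("single-variant panel: H3 undefined, reported as 0", call. = FALSE)
  }
  pph <- exp(lh - logsumexp(lh))
  pph <- pph / sum(pph)

  lpost4 <- (labf1 + labf2) - ls12
  h4_post <- exp(lpost4)
  h4_post <- h4_post / sum(h4_post)
  names(h4_post) <- panel$variant_id
  top <- which.max(h4_post)

  structure(list(region_id = panel$region_id, pph = pph,
                 h4_posterior = h4_post,
                 top_variant = panel$variant_id[top],
                 top_variant_h4 = unname(h4_post[top]),
                 colocalized = unname(pph["H4"] > 0.95),
                 n_variants = k),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %s (%d variants): PPH0-4 = %s; top variant %s (H4 posterior %.3f)%s\n",
              x$region_id, x$n_variants,
              paste(sprintf("%.3f", x$pph), collapse = " "),
              x$top_variant, x$top_variant_h4,
              if (x$colocalized) " [colocalized]" else ""))
  invisible(x)
}

#' Tabulate colocalization results across regions
#'
#' One row per region — region id, variant count, PPH0..PPH4, top variant
#' and its per-variant H4 posterior — suitable for writing the region TSV.
#'
#' @param results list of `coloc_result` objects.
#' @return data.frame.
#' @export
coloc_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    data.frame(region_id = x$region_id, n_variants = x$n_variants,
               PPH0 = x$pph[["H0"]], PPH1 = x$pph[["H1"]],
               PPH2 = x$pph[["H2"]], PPH3 = x$pph[["H3"]],
               PPH4 = x$pph[["H4"]], top_variant = x$top_variant,
               top_variant_H4 = x$top_variant_h4,
               colocalized = x$colocalized, stringsAsFactors = FALSE)
  }))
}
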