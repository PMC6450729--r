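## LD score regression: observed-scale heritability and bivariate genetic
## correlation from GWAS z-scores, with delete-one-block jackknife SEs.
##
## Model: E[chi2_j] = 1 + n * h2 * l_j / M (+ confounding inflation in the
## intercept); E[z1_j z2_j] = sqrt(n1 n2) * gencov * l_j / M + an intercept
## absorbing sample overlap.

#' LD-score table
#'
#' @param variant_id,chrom,pos per-variant identifiers.
#' @param ldscore nonnegative LD scores (sum of squared correlations with
#'   the reference panel; typically >= 1).
#' @param M total reference variant count used as the heritability
#'   denominator.
#' @return object of class `ldscore_table`.
#' @export
ldscore_table <- function(variant_id, chrom, pos, ldscore, M) {
  stopifnot(all(ldscore >= 0), M > 0,
            length(variant_id) == length(ldscore))
  structure(list(data = data.frame(variant_id = as.character(variant_id),
                                   chrom = chrom, pos = pos,
                                   ldscore = as.numeric(ldscore),
                                   stringsAsFactors = FALSE),
                 M = M),
            class = "ldscore_table")
}

#' Read LD scores in the de-facto ldscore layout
#'
#' A TSV with columns CHR, SNP, BP, L2 plus a sidecar "M file" holding the
#' single reference-panel variant count.
#'
#' @param path ldscore TSV path.
#' @param m_path M-file path (one number).
#' @return an [ldscore_table].
#' @export
read_ldscore_table <- function(path, m_path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  stopifnot(all(c("CHR", "SNP", "BP", "L2") %in% names(d)))
  M <- as.numeric(readLines(m_path, warn = FALSE)[1])
  ldscore_table(d$SNP, d$CHR, d$BP, d$L2, M)
}

## weighted regression of y on [1, x] with contiguous-block sufficient
## statistics; returns the full fit plus every leave-one-block fit
block_wls <- function(y, x, w, n_blocks) {
  p <- length(y)
  blocks <- cut(seq_len(p), breaks = n_blocks, labels = FALSE)
  X <- cbind(1, x)
  xtwx <- array(0, c(2, 2, n_blocks))
  xtwy <- matrix(0, 2, n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- blocks == b
    Xb <- X[idx, , drop = FALSE]
    xtwx[, , b] <- crossprod(Xb, Xb * w[idx])
    xtwy[, b] <- crossprod(Xb, w[idx] * y[idx])
  }
  tot_xx <- apply(xtwx, c(1, 2), sum)
  tot_xy <- rowSums(xtwy)
  full <- drop(solve(tot_xx, tot_xy))
  loo <- vapply(seq_len(n_blocks), function(b) {
    drop(solve(tot_xx - xtwx[, , b], tot_xy - xtwy[, b]))
  }, numeric(2))
  list(intercept = full[1], slope = full[2],
       loo_intercept = loo[1, ], loo_slope = loo[2, ])
}

jackknife_se <- function(loo) {
  B <- length(loo)
  sqrt((B - 1) / B * sum((loo - mean(loo))^2))
}

## internal h2 engine; returns leave-one-block estimates for reuse by rg
ldsc_h2_engine <- function(z, n, lds, n_blocks) {
  l <- lds$data$ldscore
  p <- length(z)
  stopifnot(length(l) == p)
  if (p < 2 * n_blocks) {
    stop("fewer than 2 variants per jackknife block; reduce n_blocks",
         call. = FALSE)
  }
  M <- lds$M
  nbar <- mean(n)
  chi2 <- z^2
  lw <- pmax(l, 1)
  fit <- block_wls(chi2, l, rep(1, p), n_blocks)  # unweighted initial fit
  h2 <- fit$slope * M / nbar
  for (iter in 1:2) {
    h2c <- min(max(h2, 0), 1)
    w <- 1 / (lw * (1 + nbar * h2c * lw / M)^2)
    fit <- block_wls(chi2, l, w, n_blocks)
    h2 <- fit$slope * M / nbar
  }
  list(h2 = h2, intercept = fit$intercept,
       loo_h2 = fit$loo_slope * M / nbar,
       loo_intercept = fit$loo_intercept,
       weights = w, nbar = nbar)
}

#' LD score regression heritability
#'
#' Regresses per-variant chi-squared statistics on LD scores with a free
#' intercept; `slope * M / mean(n)` is the observed-scale SNP heritability.
#' Regression weights `1 / (l * (1 + n h2 l / M)^2)` are iterated twice
#' from an unweighted initial fit; SEs come from a delete-one-block
#' jackknife over contiguous genome blocks.
#'
#' @param z per-variant z-scores, aligned with `lds`.
#' @param n per-variant (or scalar) GWAS sample size.
#' @param lds an [ldscore_table].
#' @param n_blocks jackknife blocks (default 200).
#' @return list with `h2`, `h2_se`, `intercept`, `intercept_se`,
#'   `n_blocks`.
#' @export
ldsc_h2 <- function(z, n, lds, n_blocks = 200L) {
  e <- ldsc_h2_engine(z, n, lds, n_blocks)
  list(h2 = e$h2, h2_se = jackknife_se(e$loo_h2),
       intercept = e$intercept, intercept_se = jackknife_se(e$loo_intercept),
       n_blocks = n_blocks)
}

#' Bivariate LD score regression genetic correlation
#'
#' Estimates each trait's heritability, then regresses the z-score product
#' on LD scores with a free intercept: `slope * M / sqrt(n1 n2)` is the
#' genetic covariance and the intercept absorbs sample overlap. The
#' product regression is weighted by the geometric mean of the two
#' univariate weight functions, which makes `rg(trait, itself) = 1` hold
#' exactly. `rg = gencov / sqrt(h2_1 h2_2)`; its SE is the jackknife SE of
#' the leave-one-block rg values (all three regressions share blocks).
#'
#' @param z1,z2 z-scores aligned on shared variants (and with `lds`).
#' @param n1,n2 per-variant or scalar sample sizes.
#' @param lds an [ldscore_table].
#' @param n_blocks jackknife blocks.
#' @return object of class `rg_result`: `h2_1`, `h2_2` (with SEs),
#'   `gencov` (with SE), `rg`, `rg_se`, `rg_pval`, `intercepts` (named:
#'   trait1, trait2, bivariate, with SEs), `n_blocks`. When either
#'   heritability estimate is <= 0, `rg` is `NA` with a `reason` code
#'   (such traits are unusable for genetic correlation).
#' @export
ldsc_rg <- function(z1, z2, n1, n2, lds, n_blocks = 200L) {
  stopifnot(length(z1) == length(z2))
  e1 <- ldsc_h2_engine(z1, n1, lds, n_blocks)
  e2 <- ldsc_h2_engine(z2, n2, lds, n_blocks)
  l <- lds$data$ldscore
  M <- lds$M
  nn <- sqrt(e1$nbar * e2$nbar)
  w <- sqrt(e1$weights * e2$weights)
  fit <- block_wls(z1 * z2, l, w, n_blocks)
  gencov <- fit$slope * M / nn
  loo_gencov <- fit$loo_slope * M / nn

  res <- structure(list(
    h2_1 = e1$h2, h2_1_se = jackknife_se(e1$loo_h2),
    h2_2 = e2$h2, h2_2_se = jackknife_se(e2$loo_h2),
    gencov = gencov, gencov_se = jackknife_se(loo_gencov),
    rg = NA_real_, rg_se = NA_real_, rg_pval = NA_real_,
    intercepts = c(trait1 = e1$intercept, trait2 = e2$intercept,
                   bivariate = fit$intercept),
    intercept_ses = c(trait1 = jackknife_se(e1$loo_intercept),
                      trait2 = jackknife_se(e2$loo_intercept),
                      bivariate = jackknife_se(fit$loo_intercept)),
    n_blocks = n_blocks, reason = NA_character_),
    class = "rg_result")

  if (e1$h2 <= 0 || e2$h2 <= 0) {
    res$reason <- "nonpositive heritability"
    return(res)
  }
  res$rg <- gencov / sqrt(e1$h2 * e2$h2)
  loo_rg <- loo_gencov / sqrt(pmax(e1$loo_h2, 1e-12) * pmax(e2$loo_h2, 1e-12))
  res$rg_se <- jackknife_se(loo_rg)
  res$rg_pval <- if (res$rg_se > 0) pval_norm(res$rg / res$rg_se) else NA_real_
  res
}

#' @export
print.rg_result <- function(x, ...) {
  if (is.na(x$rg)) {
    cat(sprintf("<rg_result> undefined (%s); h2 = %.3f / %.3f\n",
                x$reason, x$h2_1, x$h2_2))
  } else {
    cat(sprintf("<rg_result> rg = %.3f (se %.3f, p = %.3g); h2 = %.3f / %.3f; bivariate intercept = %.3f\n",
                x$rg, x$rg_se, x$rg_pval, x$h2_1, x$h2_2,
                x$intercepts[["bivariate"]]))
  }
  invisible(x)
}
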