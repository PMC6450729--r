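## Two-sample MR estimators and sensitivity analyses on a harmonized set.
##
## Conventions (documented in the methods vignette): multiplicative
## random-effects IVW with the residual scale floored at 1 is the default;
## Egger p-values use t with k-2 df, IVW p-values the normal reference;
## the weighted-median SE comes from a seeded parametric bootstrap.

#' Single MR estimate container
#'
#' @param method one of `"wald"`, `"ivw"`, `"egger_slope"`,
#'   `"egger_intercept"`, `"weighted_median"`.
#' @param beta,se estimate and standard error (log-odds scale for binary
#'   outcomes).
#' @param pval two-sided p-value.
#' @param k instrument count.
#' @param seed RNG seed used (bootstrap methods), or `NA`.
#' @return object of class `mr_result` with an odds-ratio 95% CI attached.
#' @export
mr_result <- function(method, beta, se, pval, k, seed = NA_integer_) {
  stopifnot(se > 0, k >= 1)
  ci <- or_ci(beta, se)
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 or = unname(ci["or"]), or_lo = unname(ci["lo"]),
                 or_hi = unname(ci["hi"]), k = as.integer(k), seed = seed),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: beta = %.4g (se %.4g), OR %.3f [%.3f-%.3f], p = %.3g, k = %d\n",
              x$method, x$beta, x$se, x$or, x$or_lo, x$or_hi, x$pval, x$k))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se, pval = x$pval,
             or = x$or, or_lo = x$or_lo, or_hi = x$or_hi, k = x$k,
             seed = x$seed, stringsAsFactors = FALSE)
}

#' Wald ratio for one instrument
#'
#' The per-variant causal estimate: the outcome effect divided by the
#' exposure effect, with the first-order delta-method standard error
#' `se_out / |beta_exp|`. A second-order correction (adding the exposure
#' sampling variance) is available via `second_order`.
#'
#' @param beta_exp exposure effect (must be nonzero).
#' @param beta_out outcome effect.
#' @param se_out outcome standard error.
#' @param se_exp exposure standard error (only used when
#'   `second_order = TRUE`).
#' @param second_order use the second-order delta SE.
#' @return list with `ratio` and `se`.
#' @export
wald_ratio <- function(beta_exp, beta_out, se_out, se_exp = NULL,
                       second_order = FALSE) {
  if (any(beta_exp == 0)) stop("null instrument", call. = FALSE)
  ratio <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  if (second_order) {
    stopifnot(!is.null(se_exp))
    se <- sqrt(se_out^2 / beta_exp^2 +
                 beta_out^2 * se_exp^2 / beta_exp^4)
  }
  list(ratio = ratio, se = se)
}

#' Cochran's Q heterogeneity statistics
#'
#' @param Q Cochran's Q.
#' @param df degrees of freedom (k - 1).
#' @return list of class `het_stats`: `Q`, `df`, `Q_pval`, and
#'   `I2 = max(0, (Q - df)/Q)`.
#' @export
het_stats <- function(Q, df) {
  structure(list(Q = Q, df = as.integer(df),
                 Q_pval = if (df >= 1) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
                 I2 = if (Q > 0) max(0, (Q - df) / Q) else 0),
            class = "het_stats")
}

#' Inverse-variance-weighted MR estimate
#'
#' Precision-weighted pooled Wald ratio — equivalently a zero-intercept
#' weighted regression of outcome on exposure effects, constrained through
#' the origin. Weights are `beta_exp^2 / se_out^2` (first-order). For k > 1
#' the default multiplicative random-effects model scales the fixed-effect
#' SE by `max(1, sqrt(Q/(k-1)))`; `model = "fixed"` disables the scaling.
#' P-values use the normal reference.
#'
#' @param h a [harmonized_set].
#' @param model `"random"` (default) or `"fixed"`.
#' @return list with `result` (an [mr_result]) and `het` (a [het_stats],
#'   `NULL` when k = 1).
#' @export
ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  k <- n_instruments(h)
  wr <- wald_ratio(h$beta_exp, h$beta_out, h$se_out)
  w <- h$beta_exp^2 / h$se_out^2
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  if (k > 1) {
    Q <- sum(w * (wr$ratio - beta)^2)
    scale <- if (model == "random") max(1, sqrt(Q / (k - 1))) else 1
    se <- se_fixed * scale
    het <- het_stats(Q, k - 1)
  } else {
    se <- se_fixed
    het <- NULL
  }
  list(result = mr_result("ivw", beta, se, pval_norm(beta / se), k), het = het)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept (weights `1 / se_out^2`), after re-orienting every
#' instrument so the exposure effect is non-negative. A nonzero intercept
#' indicates directional horizontal pleiotropy. Standard errors are scaled
#' by `max(1, residual scale)`; p-values use t with k - 2 df.
#'
#' @param h a [harmonized_set] with k >= 3.
#' @return list with `slope` and `intercept`, both [mr_result]s.
#' @export
mr_egger <- function(h) {
  k <- n_instruments(h)
  if (k < 3) stop("insufficient instruments for Egger", call. = FALSE)
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, X * w)
  co <- drop(solve(XtWX, crossprod(X, w * by)))
  resid <- by - drop(X %*% co)
  sigma2 <- sum(w * resid^2) / (k - 2)
  se_unit <- sqrt(diag(solve(XtWX)))        # SEs at unit residual variance
  se <- se_unit * max(1, sqrt(sigma2))
  list(
    slope = mr_result("egger_slope", co[["slope"]], se[["slope"]],
                      pval_t(co[["slope"]] / se[["slope"]], k - 2), k),
    intercept = mr_result("egger_intercept", co[["intercept"]], se[["intercept"]],
                          pval_t(co[["intercept"]] / se[["intercept"]], k - 2), k)
  )
}

## weighted median of `values` at cumulative weight 0.5 via the
## cumulative-midpoint interpolation rule
weighted_median_est <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(v[1])
  if (0.5 >= s[length(s)]) return(v[length(v)])
  stats::approx(s, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' The weight-0.5 quantile of the Wald ratios (cumulative-midpoint
#' interpolation), consistent when up to half the instrument weight comes
#' from invalid instruments. The SE is a seeded parametric bootstrap:
#' exposure and outcome effects are resampled from normals with their
#' reported SEs, the median recomputed, and the standard deviation taken.
#'
#' @param h a [harmonized_set] with k >= 3.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed, recorded in the result.
#' @return an [mr_result].
#' @export
weighted_median <- function(h, n_boot = 1000L, seed = 1L) {
  k <- n_instruments(h)
  if (k < 3) stop("insufficient instruments for weighted median", call. = FALSE)
  wr <- wald_ratio(h$beta_exp, h$beta_out, h$se_out)
  w <- h$beta_exp^2 / h$se_out^2
  est <- weighted_median_est(wr$ratio, w)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bx <- matrix(stats::rnorm(k * n_boot, h$beta_exp, h$se_exp), nrow = k)
  by <- matrix(stats::rnorm(k * n_boot, h$beta_out, h$se_out), nrow = k)
  boots <- vapply(seq_len(n_boot), function(b) {
    bxb <- bx[, b]
    bxb[bxb == 0] <- .Machine$double.eps
    weighted_median_est(by[, b] / bxb, bxb^2 / h$se_out^2)
  }, numeric(1))
  se <- stats::sd(boots)
  mr_result("weighted_median", est, se, pval_norm(est / se), k, seed = seed)
}

## preserve caller RNG state so seeded internals do not perturb the session
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate k times, omitting each instrument in turn,
#' plus an `"all"` row. `no_single_driver` is TRUE when every leave-one-out
#' estimate keeps the full-set sign and its 95% CI contains the full-set
#' estimate — i.e. no single SNP accounts for the association.
#'
#' @param h a [harmonized_set] with k >= 2.
#' @param model passed to [ivw()].
#' @return list with `table` (data.frame: left_out, beta, se, pval, k) and
#'   `no_single_driver` (logical).
#' @export
leave_one_out <- function(h, model = "random") {
  k <- n_instruments(h)
  if (k < 2) stop("leave-one-out needs k >= 2", call. = FALSE)
  full <- ivw(h, model)$result
  rows <- lapply(seq_len(k), function(i) {
    sub <- harmonized_set(h$variant_ids[-i], h$beta_exp[-i], h$se_exp[-i],
                          h$beta_out[-i], h$se_out[-i],
                          exposure_id = h$exposure_id, outcome_id = h$outcome_id)
    r <- ivw(sub, model)$result
    data.frame(left_out = h$variant_ids[i], beta = r$beta, se = r$se,
               pval = r$pval, k = r$k, stringsAsFactors = FALSE)
  })
  tab <- rbind(do.call(rbind, rows),
               data.frame(left_out = "all", beta = full$beta, se = full$se,
                          pval = full$pval, k = full$k, stringsAsFactors = FALSE))
  loo <- tab[tab$left_out != "all", ]
  ok <- sign(loo$beta) == sign(full$beta) &
    full$beta >= loo$beta - 1.96 * loo$se &
    full$beta <= loo$beta + 1.96 * loo$se
  list(table = tab, no_single_driver = all(ok))
}

#' Steiger directionality test
#'
#' Compares the variance explained by the instruments in the exposure vs
#' the outcome study. Per-instrument `r2 = z^2 / (z^2 + n - 2)` (observed
#' scale; a liability-scale correction for binary traits is out of scope)
#' summed per study; the z statistic is the difference of
#' Fisher-transformed sqrt(r2) values using the effective sample size
#' `min(n_exp, n_out)`. The causal direction is supported when the
#' instruments explain more variance in the exposure.
#'
#' @param h a [harmonized_set].
#' @param n_exp,n_out study sample sizes (default: taken from `h`).
#' @return list of class `steiger_result`: `r2_exp`, `r2_out`,
#'   `direction_ok`, `z`, `pval`.
#' @export
steiger <- function(h, n_exp = h$n_exp, n_out = h$n_out) {
  if (is.na(n_exp) || is.na(n_out) || n_exp <= 0 || n_out <= 0) {
    stop("steiger requires positive sample sizes", call. = FALSE)
  }
  z_exp <- h$beta_exp / h$se_exp
  z_out <- h$beta_out / h$se_out
  r2_exp <- sum(z_exp^2 / (z_exp^2 + n_exp - 2))
  r2_out <- sum(z_out^2 / (z_out^2 + n_out - 2))
  n_eff <- min(n_exp, n_out)
  z <- (atanh(sqrt(pmin(r2_exp, 1 - 1e-12))) -
          atanh(sqrt(pmin(r2_out, 1 - 1e-12)))) / sqrt(2 / (n_eff - 3))
  structure(list(r2_exp = r2_exp, r2_out = r2_out,
                 direction_ok = r2_exp > r2_out,
                 z = z, pval = pval_norm(z)),
            class = "steiger_result")
}

#' Mean instrument F-statistic
#'
#' Mean per-instrument `beta_exp^2 / se_exp^2`; values above 10 are
#' conventionally labeled strong instruments (weak-instrument bias is a
#' concern below that).
#'
#' @param h a [harmonized_set].
#' @return numeric F, with attribute `strong` (F > 10).
#' @export
f_statistic <- function(h) {
  f <- mean(h$beta_exp^2 / h$se_exp^2)
  attr(f, "strong") <- f > 10
  f
}

#' Full estimator battery on one harmonized set
#'
#' IVW (+ heterogeneity), MR-Egger slope and intercept, weighted median,
#' leave-one-out summary, Steiger directionality (when sample sizes are
#' known) and the mean instrument F — the per-trait row of the screen.
#'
#' @param h a [harmonized_set].
#' @param n_boot,seed passed to [weighted_median()].
#' @param model IVW/leave-one-out effects model.
#' @return list of class `mr_battery` with components `ivw`, `het`,
#'   `egger_slope`, `egger_intercept`, `weighted_median`, `loo`, `steiger`,
#'   `f_stat`; Egger/median are `NULL` when k < 3.
#' @export
mr_battery <- function(h, n_boot = 1000L, seed = 1L, model = "random") {
  k <- n_instruments(h)
  iv <- ivw(h, model)
  eg <- if (k >= 3) mr_egger(h) else NULL
  wm <- if (k >= 3) weighted_median(h, n_boot, seed) else NULL
  loo <- if (k >= 2) leave_one_out(h, model) else NULL
  st <- if (!is.na(h$n_exp) && !is.na(h$n_out)) steiger(h) else NULL
  structure(list(ivw = iv$result, het = iv$het,
                 egger_slope = if (is.null(eg)) NULL else eg$slope,
                 egger_intercept = if (is.null(eg)) NULL else eg$intercept,
                 weighted_median = wm, loo = loo, steiger = st,
                 f_stat = f_statistic(h), k = k),
            class = "mr_battery")
}

#' @export
as.data.frame.mr_battery <- function(x, ...) {
  parts <- list(x$ivw, x$egger_slope, x$egger_intercept, x$weighted_median)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- do.call(rbind, lapply(parts, as.data.frame))
  out$Q <- if (is.null(x$het)) NA_real_ else x$het$Q
  out$Q_pval <- if (is.null(x$het)) NA_real_ else x$het$Q_pval
  out$I2 <- if (is.null(x$het)) NA_real_ else x$het$I2
  out$f_stat <- as.numeric(x$f_stat)
  out$steiger_ok <- if (is.null(x$steiger)) NA else x$steiger$direction_ok
  out$no_single_driver <- if (is.null(x$loo)) NA else x$loo$no_single_driver
  out
}

#' Reverse-direction MR
#'
#' Runs the estimator battery with the roles swapped: the original outcome
#' (e.g. the ALS GWAS, instrumented by its genome-wide-significant loci)
#' becomes the exposure and the candidate trait the outcome. A
#' nonsignificant reverse estimate supports forward causality.
#'
#' @param outcome_as_exposure [sumstats] of the original outcome.
#' @param exposure_as_outcome [sumstats] of the original exposure.
#' @param ld an [ld_matrix] for clumping.
#' @param p_thresh,min_snps instrument selection thresholds.
#' @param clump_r2,clump_window_kb clumping parameters.
#' @param n_boot,seed bootstrap controls.
#' @return an [mr_battery], or a list with `eligible = FALSE` when fewer
#'   than `min_snps` loci are available after clumping.
#' @export
reverse_mr <- function(outcome_as_exposure, exposure_as_outcome, ld,
                       p_thresh = 5e-8, min_snps = 2L, clump_r2 = 0.001,
                       clump_window_kb = 10000L, n_boot = 1000L, seed = 1L) {
  sel <- select_instruments(outcome_as_exposure, p_thresh, min_snps)
  if (!sel$eligible) return(list(eligible = FALSE, n = sel$n))
  ins <- suppressWarnings(clump(sel$instruments, ld, clump_r2, clump_window_kb))
  if (nrow(ins) < min_snps) return(list(eligible = FALSE, n = nrow(ins)))
  ids <- intersect(ins$variant_id, exposure_as_outcome$data$variant_id)
  if (length(ids) < 1) return(list(eligible = FALSE, n = 0L))
  h <- harmonize(ins[ins$variant_id %in% ids, , drop = FALSE],
                 exposure_as_outcome$data[
                   exposure_as_outcome$data$variant_id %in% ids, , drop = FALSE],
                 exposure_id = outcome_as_exposure$trait_id,
                 outcome_id = exposure_as_outcome$trait_id)
  mr_battery(h, n_boot = n_boot, seed = seed)
}
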