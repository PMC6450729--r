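## Multivariable MR: apportioning effects among correlated exposures
## instrumented by a jointly clumped union of instruments.

#' Construct a multivariable MR input
#'
#' The instrument set is the union of per-exposure instruments, jointly
#' clumped; exposure effects for variants not significant in a given
#' exposure are taken from that exposure's full summary statistics
#' (standard multivariable-MR practice).
#'
#' @param variant_ids character vector, length k.
#' @param B_exp,se_exp k x m matrices of exposure effects and SEs.
#' @param beta_out,se_out outcome effect vectors, length k.
#' @param exposure_ids character vector, length m.
#' @return object of class `mvmr_input`. Requires k > m and no all-zero
#'   exposure column.
#' @export
mvmr_input <- function(variant_ids, B_exp, se_exp, beta_out, se_out,
                       exposure_ids) {
  B_exp <- as.matrix(B_exp); se_exp <- as.matrix(se_exp)
  k <- length(variant_ids); m <- ncol(B_exp)
  stopifnot(nrow(B_exp) == k, all(dim(se_exp) == dim(B_exp)),
            length(beta_out) == k, length(se_out) == k,
            length(exposure_ids) == m, all(se_out > 0))
  if (k <= m) stop("need more instruments than exposures (k > m)", call. = FALSE)
  zero_col <- apply(B_exp, 2, function(col) all(col == 0))
  if (any(zero_col)) {
    stop("all-zero exposure column: ",
         paste(exposure_ids[zero_col], collapse = ", "), call. = FALSE)
  }
  colnames(B_exp) <- colnames(se_exp) <- exposure_ids
  structure(list(variant_ids = as.character(variant_ids), B_exp = B_exp,
                 se_exp = se_exp, beta_out = as.numeric(beta_out),
                 se_out = as.numeric(se_out),
                 exposure_ids = as.character(exposure_ids)),
            class = "mvmr_input")
}

#' Fit multivariable MR by weighted least squares
#'
#' Regresses the outcome effects on the m exposure-effect columns with no
#' intercept and weights `1 / se_out^2`. SEs are scaled by
#' `max(1, residual scale)`; p-values use t with k - m df. Also reports a
#' conditional instrument-strength F per exposure: the mean weighted
#' squared residual of that exposure's effects after regressing them on
#' the other exposures' effects, relative to its own SEs (low values flag
#' conditionally weak instruments).
#'
#' @param inp an [mvmr_input].
#' @return list of class `mvmr_result`: `table` (exposure, k, beta, se,
#'   pval), `conditional_F` (named vector), `sigma` (residual scale).
#' @export
mvmr_fit <- function(inp) {
  X <- inp$B_exp
  k <- nrow(X); m <- ncol(X)
  w <- 1 / inp$se_out^2
  qrX <- qr(X * sqrt(w))
  if (qrX$rank < m) {
    bad <- inp$exposure_ids[qrX$pivot[(qrX$rank + 1):m]]
    stop("collinear exposures: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  XtWX <- crossprod(X, X * w)
  co <- drop(solve(XtWX, crossprod(X, w * inp$beta_out)))
  resid <- inp$beta_out - drop(X %*% co)
  sigma2 <- sum(w * resid^2) / (k - m)
  se <- sqrt(diag(solve(XtWX))) * max(1, sqrt(sigma2))
  pv <- pval_t(co / se, k - m)

  cond_f <- vapply(seq_len(m), function(j) {
    bj <- X[, j]
    if (m == 1) {
      rj <- bj
    } else {
      Xo <- X[, -j, drop = FALSE]
      wj <- 1 / inp$se_exp[, j]^2
      cj <- drop(solve(crossprod(Xo, Xo * wj), crossprod(Xo, wj * bj)))
      rj <- bj - drop(Xo %*% cj)
    }
    mean(rj^2 / inp$se_exp[, j]^2)
  }, numeric(1))
  names(cond_f) <- inp$exposure_ids

  structure(list(
    table = data.frame(exposure = inp$exposure_ids, k = k, beta = unname(co),
                       se = unname(se), pval = unname(pv),
                       stringsAsFactors = FALSE),
    conditional_F = cond_f, sigma = sqrt(sigma2)),
    class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("<mvmr_result>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Lasso-based exposure selection for multivariable MR
#'
#' Fits the same weighted no-intercept regression with an L1 penalty
#' (glmnet), choosing the penalty by 10-fold cross-validation with a
#' seeded fold assignment, and returns the exposures with nonzero
#' coefficients at `lambda.1se`, refit unpenalized for inference.
#'
#' @param inp an [mvmr_input] with m >= 2.
#' @param seed fold-assignment seed (recorded in the result).
#' @param nfolds cross-validation folds.
#' @return list with `selected` (character vector, possibly empty with a
#'   warning), `fit` (the unpenalized [mvmr_fit] on the selection, or
#'   `NULL`), and `seed`.
#' @export
lasso_select <- function(inp, seed = 1L, nfolds = 10L) {
  m <- ncol(inp$B_exp)
  if (m < 2) stop("lasso selection needs m >= 2 exposures", call. = FALSE)
  k <- nrow(inp$B_exp)
  w <- 1 / inp$se_out^2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), k))
  cv <- glmnet::cv.glmnet(inp$B_exp, inp$beta_out, weights = w,
                          intercept = FALSE, standardize = TRUE,
                          foldid = foldid)
  co <- as.numeric(stats::coef(cv, s = "lambda.1se"))[-1]  # drop intercept row
  selected <- inp$exposure_ids[co != 0]
  if (!length(selected)) {
    warning("lasso shrank every exposure to zero", call. = FALSE)
    return(list(selected = character(), fit = NULL, seed = seed))
  }
  sub <- mvmr_input(inp$variant_ids,
                    inp$B_exp[, selected, drop = FALSE],
                    inp$se_exp[, selected, drop = FALSE],
                    inp$beta_out, inp$se_out, selected)
  fit <- if (length(selected) < k) mvmr_fit(sub) else NULL
  list(selected = selected, fit = fit, seed = seed)
}
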