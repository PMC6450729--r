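## Weighted genetic risk score on individual-level dosages, with
## quintile-based logistic regression, covariate adjustment and
## per-stratum reruns.

#' Cohort container for risk-score analysis
#'
#' @param sample_ids character vector, length n.
#' @param dosage n x k numeric matrix in \[0, 2\], columns named by variant
#'   id (NAs allowed; they are mean-imputed when scoring).
#' @param phenotype 0/1 integer vector (1 = case).
#' @param covariates data.frame of per-sample covariates (e.g. sex, age
#'   and 20 principal components), or `NULL`.
#' @param strata named list of logical vectors (e.g. `c9orf72_carrier`,
#'   `familial`, `sporadic`, `male`, `female`), or `NULL`.
#' @return object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(sample_ids, dosage, phenotype, covariates = NULL,
                          strata = NULL) {
  dosage <- as.matrix(dosage)
  n <- length(sample_ids)
  stopifnot(nrow(dosage) == n, length(phenotype) == n,
            all(phenotype %in% c(0L, 1L)),
            all(is.na(dosage) | (dosage >= 0 & dosage <= 2)))
  if (is.null(colnames(dosage))) stop("dosage columns must be named by variant id")
  if (!is.null(covariates)) stopifnot(nrow(covariates) == n)
  if (!is.null(strata)) stopifnot(all(vapply(strata, length, 1L) == n))
  structure(list(sample_ids = as.character(sample_ids), dosage = dosage,
                 phenotype = as.integer(phenotype), covariates = covariates,
                 strata = strata),
            class = "cohort_matrix")
}

#' Compute a weighted genetic risk score
#'
#' `score_s = sum_v dosage_{s,v} * weight_v` over the variants shared
#' between the weight map and the dosage columns; missing dosages are
#' mean-imputed per variant. Dosages are assumed already oriented to each
#' weight's effect allele. The weight source is configurable upstream:
#' exposure-GWAS betas or outcome-GWAS betas (the screen's default follows
#' the latter convention for its LDL score).
#'
#' @param cohort a [cohort_matrix].
#' @param weights named numeric vector (variant id -> weight).
#' @return numeric score vector, one per sample.
#' @export
compute_grs <- function(cohort, weights) {
  shared <- intersect(names(weights), colnames(cohort$dosage))
  if (!length(shared)) stop("zero overlapping variants between weights and dosages",
                            call. = FALSE)
  D <- cohort$dosage[, shared, drop = FALSE]
  for (j in seq_len(ncol(D))) {
    miss <- is.na(D[, j])
    if (any(miss)) D[miss, j] <- mean(D[, j], na.rm = TRUE)
  }
  drop(D %*% weights[shared])
}

## deterministic score quantile groups: ties broken by sample_id order
score_quantile_groups <- function(scores, sample_ids, n_groups) {
  ord <- order(scores, sample_ids)
  grp <- integer(length(scores))
  grp[ord] <- ceiling(seq_along(ord) / (length(ord) / n_groups))
  pmin(grp, n_groups)
}

## Firth-penalized logistic regression (Jeffreys prior); used as the
## fallback when ordinary ML shows quasi-separation
firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XtWX <- crossprod(X, X * w)
    XtWX_inv <- solve(XtWX)
    h <- rowSums((X %*% XtWX_inv) * X) * w      # hat-matrix diagonal
    U <- crossprod(X, (y - p) + h * (0.5 - p))
    step <- drop(XtWX_inv %*% U)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  list(coef = b, se = sqrt(diag(XtWX_inv)), converged = it < max_iter)
}

#' Quintile logistic regression of disease on a genetic risk score
#'
#' Splits the analyzed sample into `n_groups` equal-size score groups
#' (quintiles by default; ties resolved deterministically by sample id),
#' then fits a logistic regression of disease on indicator-coded groups
#' 2..n vs the lowest (reference) group, adjusted for the stated
#' covariates. Wald 95% CIs; a trend p-value from the model with group
#' entered as a single numeric term; per-stratum reruns for every stratum
#' label. Quasi-separation triggers a flagged Firth-penalized refit.
#'
#' @param scores numeric score vector from [compute_grs()].
#' @param cohort a [cohort_matrix].
#' @param adjust character vector of covariate column names (e.g.
#'   `c("sex", "age", paste0("PC", 1:20))`); empty for unadjusted.
#' @param n_groups number of score groups (default 5).
#' @param min_per_group warn when any group holds fewer samples.
#' @return list of class `grs_result`: `table` (group, n_cases,
#'   n_controls, or, or_lo, or_hi, pval — reference group OR fixed at 1),
#'   `trend_pval`, `firth` (logical), `strata` (named list of the same
#'   structure per stratum).
#' @export
quintile_logistic <- function(scores, cohort, adjust = character(),
                              n_groups = 5L, min_per_group = 50L) {
  ## drop aliased columns (e.g. a sex covariate inside a single-sex
  ## stratum) so the fit stays full rank; the intercept is always kept
  drop_aliased <- function(X) {
    q <- qr(X)
    if (q$rank < ncol(X)) X <- X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
    X
  }
  run_one <- function(keep) {
    s <- scores[keep]
    y <- cohort$phenotype[keep]
    ids <- cohort$sample_ids[keep]
    grp <- score_quantile_groups(s, ids, n_groups)
    if (min(table(factor(grp, levels = seq_len(n_groups)))) < min_per_group) {
      warning("fewer than ", min_per_group, " samples in a score group",
              call. = FALSE)
    }
    G <- stats::model.matrix(~ factor(grp, levels = seq_len(n_groups)))[, -1, drop = FALSE]
    colnames(G) <- paste0("q", 2:n_groups)
    X <- cbind(`(Intercept)` = 1, G)
    if (length(adjust)) {
      C <- as.matrix(cohort$covariates[keep, adjust, drop = FALSE])
      X <- cbind(X, C)
    }
    X <- drop_aliased(X)
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    mu <- fit$fitted.values
    sep <- any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(fit$coefficients) > 15) ||
      !fit$converged
    if (sep) {
      ff <- firth_logistic(X, y)
      co <- ff$coef; se <- ff$se
    } else {
      w <- mu * (1 - mu)
      co <- fit$coefficients
      se <- sqrt(diag(solve(crossprod(X, X * w))))
    }
    qi <- seq(2, n_groups)
    idx <- match(paste0("q", qi), colnames(X))
    rows <- data.frame(
      group = seq_len(n_groups),
      n_cases = as.integer(tapply(y, grp, sum)[as.character(seq_len(n_groups))]),
      n_controls = as.integer(tapply(1 - y, grp, sum)[as.character(seq_len(n_groups))]),
      or = c(1, exp(co[idx])),
      or_lo = c(NA, exp(co[idx] - 1.96 * se[idx])),
      or_hi = c(NA, exp(co[idx] + 1.96 * se[idx])),
      pval = c(NA, pval_norm(co[idx] / se[idx])),
      stringsAsFactors = FALSE
    )
    ## trend model: group index as one numeric term
    Xt <- cbind(`(Intercept)` = 1, trend = grp)
    if (length(adjust)) Xt <- cbind(Xt, as.matrix(cohort$covariates[keep, adjust, drop = FALSE]))
    Xt <- drop_aliased(Xt)
    tfit <- suppressWarnings(stats::glm.fit(Xt, y, family = stats::binomial()))
    tw <- tfit$fitted.values * (1 - tfit$fitted.values)
    tse <- sqrt(diag(solve(crossprod(Xt, Xt * tw))))
    trend_p <- pval_norm(tfit$coefficients[["trend"]] / tse[[which(colnames(Xt) == "trend")]])
    list(table = rows, trend_pval = trend_p, firth = sep)
  }

  all_res <- run_one(rep(TRUE, length(scores)))
  strata_res <- NULL
  if (!is.null(cohort$strata)) {
    strata_res <- lapply(cohort$strata, function(keep) run_one(keep))
  }
  structure(list(table = all_res$table, trend_pval = all_res$trend_pval,
                 firth = all_res$firth, strata = strata_res,
                 n_groups = n_groups),
            class = "grs_result")
}

#' @export
print.grs_result <- function(x, ...) {
  cat(sprintf("<grs_result> %d score groups, trend p = %.3g%s\n",
              x$n_groups, x$trend_pval, if (x$firth) " (Firth fallback)" else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}
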