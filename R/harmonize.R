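## Building a valid instrument set: genome-wide filter, greedy LD clumping,
## optional proxy substitution, and allele harmonization between the
## exposure and outcome studies.

#' Select genome-wide-significant instruments for an exposure
#'
#' Keeps records with `pval < p_thresh` (default 5e-8). An exposure with
#' fewer than `min_snps` (default 2) qualifying variants is flagged
#' ineligible — a status, not an exception — mirroring the screening rule
#' that an exposure needs at least two associated SNPs.
#'
#' @param exp a [sumstats] object.
#' @param p_thresh significance threshold in (0, 1\].
#' @param min_snps minimum instrument count for eligibility.
#' @return list with `instruments` (data.frame of qualifying records),
#'   `eligible` (logical) and `n` (count).
#' @export
select_instruments <- function(exp, p_thresh = 5e-8, min_snps = 2L) {
  stopifnot(p_thresh > 0, p_thresh <= 1)
  ins <- exp$data[exp$data$pval < p_thresh, , drop = FALSE]
  rownames(ins) <- NULL
  list(instruments = ins, eligible = nrow(ins) >= min_snps, n = nrow(ins))
}

#' Greedy LD clumping of associated variants
#'
#' Sorts records by ascending p-value (ties broken by variant id, making
#' the result invariant to input order), repeatedly keeps the best
#' remaining record and discards all records on the same chromosome within
#' +/- `window_kb` whose r-squared with it is >= `r2_thresh`. Records not
#' resolvable in the LD panel are retained with a warning (strict mode
#' drops them instead). Output is sorted by (chrom, pos).
#'
#' @param records data.frame of variant records (needs `variant_id`,
#'   `pval`; `chrom`/`pos` taken from the LD panel when missing).
#' @param ld an [ld_matrix].
#' @param r2_thresh r-squared threshold in (0, 1\]; default 0.001.
#' @param window_kb half-window in kb (intra-chromosomal); default 10000
#'   (i.e. +/- 10 Mb).
#' @param strict drop unresolvable records instead of keeping them.
#' @return data.frame of retained records, attribute `unclumpable` holding
#'   the ids kept without LD information.
#' @export
clump <- function(records, ld, r2_thresh = 0.001, window_kb = 10000L,
                  strict = FALSE) {
  if (r2_thresh <= 0 || r2_thresh > 1) {
    stop("r2_thresh must be in (0, 1]", call. = FALSE)
  }
  if (!nrow(records)) return(records)
  d <- records
  pidx <- match(d$variant_id, ld$positions$variant_id)
  if (!"chrom" %in% names(d)) d$chrom <- NA_character_
  if (!"pos" %in% names(d)) d$pos <- NA_integer_
  fill <- is.na(d$chrom) | is.na(d$pos)
  d$chrom[fill] <- ld$positions$chrom[pidx[fill]]
  d$pos[fill] <- ld$positions$pos[pidx[fill]]

  in_panel <- !is.na(match(d$variant_id, ld$variant_ids))
  unclumpable <- d$variant_id[!in_panel]
  if (length(unclumpable)) {
    warning("variants absent from the LD panel kept unclumped: ",
            paste(unclumpable, collapse = ", "), call. = FALSE)
    if (strict) {
      d <- d[in_panel, , drop = FALSE]
      in_panel <- rep(TRUE, nrow(d))
      unclumpable <- character()
    }
  }

  ord <- order(d$pval, d$variant_id)
  d <- d[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(d))
  kept <- logical(nrow(d))
  ridx <- match(d$variant_id, ld$variant_ids)
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    if (is.na(ridx[i])) next  # unclumpable index variant prunes nothing
    cand <- which(alive & d$chrom == d$chrom[i] &
                    abs(d$pos - d$pos[i]) <= window_kb * 1000 &
                    !is.na(ridx))
    if (length(cand)) {
      r2 <- ld$r[ridx[i], ridx[cand]]^2
      alive[cand[r2 >= r2_thresh]] <- FALSE
    }
  }
  out <- d[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unclumpable") <- unclumpable
  out
}

#' Find an LD proxy in the outcome panel for a missing variant
#'
#' Returns the outcome record with maximal r-squared >= `r2_min` (default
#' 0.8) to the missing exposure variant, together with the signed LD
#' correlation `r`: when the proxy is substituted, the exposure effect must
#' be re-signed by `sign(r)`.
#'
#' @param missing a single-row data.frame (the exposure record absent from
#'   the outcome) or a variant id.
#' @param outcome a [sumstats] object.
#' @param ld an [ld_matrix].
#' @param r2_min minimum r-squared for a usable proxy.
#' @return list with `record` (the proxy's outcome row), `proxy_id`, `r`;
#'   or `NULL` when no proxy qualifies.
#' @export
proxy_lookup <- function(missing, outcome, ld, r2_min = 0.8) {
  id <- if (is.character(missing)) missing else missing$variant_id
  i <- match(id, ld$variant_ids)
  if (is.na(i)) return(NULL)
  cand_ids <- setdiff(intersect(outcome$data$variant_id, ld$variant_ids), id)
  if (!length(cand_ids)) return(NULL)
  r <- ld$r[i, match(cand_ids, ld$variant_ids)]
  best <- which.max(r^2)
  if (r[best]^2 < r2_min) return(NULL)
  rec <- outcome$data[match(cand_ids[best], outcome$data$variant_id), , drop = FALSE]
  list(record = rec, proxy_id = cand_ids[best], r = unname(r[best]))
}

#' Construct a harmonized instrument set directly
#'
#' Low-level constructor for an already-aligned set of instruments (used by
#' the simulators and by [harmonize()]); every vector has length k and the
#' exposure effect allele is the same in both studies.
#'
#' @param variant_ids character vector, length k.
#' @param beta_exp,se_exp,beta_out,se_out numeric vectors, length k;
#'   standard errors strictly positive.
#' @param eaf_exp optional effect-allele frequencies.
#' @param exposure_id,outcome_id trait labels.
#' @param n_exp,n_out study sample sizes.
#' @param flips,dropped_palindromes harmonization bookkeeping counts.
#' @param proxies_used named character vector (variant -> proxy id).
#' @return object of class `harmonized_set`.
#' @export
harmonized_set <- function(variant_ids, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NULL, exposure_id = "exposure",
                           outcome_id = "outcome", n_exp = NA_real_,
                           n_out = NA_real_, flips = 0L,
                           dropped_palindromes = 0L,
                           proxies_used = character()) {
  k <- length(variant_ids)
  stopifnot(k >= 1,
            length(beta_exp) == k, length(se_exp) == k,
            length(beta_out) == k, length(se_out) == k,
            all(se_exp > 0), all(se_out > 0))
  if (!is.null(eaf_exp)) stopifnot(length(eaf_exp) == k)
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome_id,
         variant_ids = as.character(variant_ids),
         beta_exp = as.numeric(beta_exp), se_exp = as.numeric(se_exp),
         beta_out = as.numeric(beta_out), se_out = as.numeric(se_out),
         eaf_exp = if (is.null(eaf_exp)) NULL else as.numeric(eaf_exp),
         n_exp = n_exp, n_out = n_out,
         flips = flips, dropped_palindromes = dropped_palindromes,
         proxies_used = proxies_used),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: k = %d (%d flipped, %d palindromes dropped)\n",
              x$exposure_id, x$outcome_id, length(x$variant_ids),
              x$flips, x$dropped_palindromes))
  invisible(x)
}

#' Number of instruments in a harmonized set
#' @param h a `harmonized_set`.
#' @return integer k.
#' @export
n_instruments <- function(h) length(h$variant_ids)

#' Harmonize exposure and outcome effect alleles
#'
#' Aligns the paired records onto a common effect-allele orientation:
#' \itemize{
#'   \item same allele pair, same orientation — kept unchanged;
#'   \item swapped alleles — outcome beta negated, outcome eaf complemented;
#'   \item strand-complement pair (e.g. A/G vs T/C) — re-complemented, then
#'     the two rules above apply;
#'   \item palindromic pair (A/T or C/G) — orientation resolved by
#'     effect-allele-frequency agreement when both frequencies lie outside
#'     \[band, 1 - band\]; otherwise dropped as ambiguous;
#'   \item incompatible allele sets — dropped.
#' }
#'
#' @param exp_records,out_records data.frames of variant records paired by
#'   `variant_id` (the intersection is taken; column layout as in
#'   `sumstats$data`).
#' @param palindrome_maf_band ambiguity band half-width; default 0.42, i.e.
#'   palindromes with either frequency in \[0.42, 0.58\] are dropped.
#' @param palindrome_action `"resolve"` (frequency-resolve then drop the
#'   ambiguous ones) or `"drop"` (drop every palindrome).
#' @param exposure_id,outcome_id,n_exp,n_out metadata for the result.
#' @param proxies_used named vector recorded verbatim in the result.
#' @return a [harmonized_set]; errors with "no harmonizable instruments"
#'   when nothing survives.
#' @export
harmonize <- function(exp_records, out_records, palindrome_maf_band = 0.42,
                      palindrome_action = c("resolve", "drop"),
                      exposure_id = "exposure", outcome_id = "outcome",
                      n_exp = NA_real_, n_out = NA_real_,
                      proxies_used = character()) {
  palindrome_action <- match.arg(palindrome_action)
  ids <- intersect(exp_records$variant_id, out_records$variant_id)
  e <- exp_records[match(ids, exp_records$variant_id), , drop = FALSE]
  o <- out_records[match(ids, out_records$variant_id), , drop = FALSE]
  if (is.null(e$eaf)) e$eaf <- NA_real_
  if (is.null(o$eaf)) o$eaf <- NA_real_

  keep <- logical(length(ids))
  flips <- 0L
  dropped_pal <- 0L
  dropped_incompat <- character()
  band_lo <- palindrome_maf_band
  band_hi <- 1 - palindrome_maf_band

  for (j in seq_along(ids)) {
    e1 <- e$effect_allele[j]; e2 <- e$other_allele[j]
    o1 <- o$effect_allele[j]; o2 <- o$other_allele[j]

    if (is_palindromic(e1, e2)) {
      if (!is_palindromic(o1, o2) || !setequal(c(o1, o2), c(e1, e2))) {
        dropped_incompat <- c(dropped_incompat, ids[j]); next
      }
      if (palindrome_action == "drop") { dropped_pal <- dropped_pal + 1L; next }
      ## align allele labels first (a label swap and a strand flip are the
      ## same operation for a palindrome; frequency is the only evidence)
      if (o1 == e2) {
        o$beta[j] <- -o$beta[j]
        o$eaf[j] <- 1 - o$eaf[j]
      }
      fe <- e$eaf[j]; fo <- o$eaf[j]
      informative <- !is.na(fe) && !is.na(fo) &&
        (fe < band_lo || fe > band_hi) && (fo < band_lo || fo > band_hi)
      if (!informative) { dropped_pal <- dropped_pal + 1L; next }
      if ((fe - 0.5) * (fo - 0.5) < 0) {
        ## frequencies disagree: the outcome study reported the other strand
        o$beta[j] <- -o$beta[j]
        o$eaf[j] <- 1 - o$eaf[j]
        flips <- flips + 1L
      }
      keep[j] <- TRUE
      next
    }

    ## strand-complement representation: re-complement the outcome alleles
    if (!setequal(c(o1, o2), c(e1, e2)) &&
        setequal(complement_alleles(c(o1, o2)), c(e1, e2))) {
      o1 <- complement_alleles(o1); o2 <- complement_alleles(o2)
    }
    if (o1 == e1 && o2 == e2) {
      keep[j] <- TRUE
    } else if (o1 == e2 && o2 == e1) {
      o$beta[j] <- -o$beta[j]
      o$eaf[j] <- 1 - o$eaf[j]
      flips <- flips + 1L
      keep[j] <- TRUE
    } else {
      dropped_incompat <- c(dropped_incompat, ids[j])
    }
  }

  if (!any(keep)) stop("no harmonizable instruments", call. = FALSE)
  if (length(dropped_incompat)) {
    warning("dropped incompatible allele sets: ",
            paste(dropped_incompat, collapse = ", "), call. = FALSE)
  }

  harmonized_set(
    variant_ids = ids[keep],
    beta_exp = e$beta[keep], se_exp = e$se[keep],
    beta_out = o$beta[keep], se_out = o$se[keep],
    eaf_exp = e$eaf[keep],
    exposure_id = exposure_id, outcome_id = outcome_id,
    n_exp = n_exp, n_out = n_out,
    flips = flips, dropped_palindromes = dropped_pal,
    proxies_used = proxies_used
  )
}
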