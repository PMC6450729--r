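## Orchestration of the two phenome-wide designs: the LDSC genetic
## correlation scan with FDR control, and the two-phase MR screen with
## cross-cohort replication.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement:
#' `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param pvals p-values in (0, 1\].
#' @param alpha significance level for the mask (default 0.05).
#' @return list with `adjusted` (same order as input) and `significant`
#'   (logical mask, `adjusted <= alpha`); empty inputs give empty outputs.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  m <- length(pvals)
  if (!m) return(list(adjusted = numeric(), significant = logical()))
  ord <- order(pvals)
  ranked <- pvals[ord] * m / seq_len(m)
  adj_sorted <- pmin(rev(cummin(rev(ranked))), 1)
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  list(adjusted = adjusted, significant = adjusted <= alpha)
}

#' Trait library for a phenome-wide screen
#'
#' @param traits named list; each element a list with `sumstats` (a
#'   [sumstats] object) and `cohort_tag` (`"published"` or `"ukbb"`), plus
#'   an optional `category` used for replication matching.
#' @param outcome the outcome [sumstats] (e.g. the ALS GWAS).
#' @return object of class `trait_library`; trait ids must be unique.
#' @export
trait_library <- function(traits, outcome) {
  ids <- names(traits)
  if (length(traits) && (is.null(ids) || anyDuplicated(ids))) {
    stop("traits must be uniquely named")
  }
  for (tr in traits) {
    stopifnot(inherits(tr$sumstats, "sumstats"),
              tr$cohort_tag %in% c("published", "ukbb"))
  }
  stopifnot(inherits(outcome, "sumstats"))
  structure(list(traits = traits, outcome = outcome), class = "trait_library")
}

#' Default screen configuration
#'
#' Thresholds follow the two-phase design: phase I keeps traits whose IVW
#' pooled estimate has p <= 0.05; the sensitivity gate additionally
#' requires MR-Egger and weighted-median p <= 0.05; replication requires a
#' sensitivity-passing, sign-concordant hit in the other cohort class when
#' a matched trait exists. No multiplicity correction is applied within
#' the MR phase (replication substitutes for it); BH-adjusted IVW
#' p-values are reported in a side column for transparency.
#'
#' @param ... overrides for any default.
#' @return named list of configuration values.
#' @export
screen_config <- function(...) {
  cfg <- list(
    p_thresh = 5e-8, min_snps = 2L,
    clump_r2 = 0.001, clump_window_kb = 10000L,
    palindrome_maf_band = 0.42,
    phase1_alpha = 0.05, sensitivity_alpha = 0.05,
    replication = c("category", "strict")[1],
    n_boot = 1000L, seed = 1L,
    fdr_alpha = 0.05, h2_bounds = c(0, 1)
  )
  utils::modifyList(cfg, list(...))
}

#' Run the two-phase MR screen over a trait library
#'
#' For every exposure: genome-wide instrument selection, LD clumping,
#' intersection with the outcome, harmonization, then the full estimator
#' battery. Gates are evaluated in order (phase I IVW, sensitivity,
#' replication) and every gate decision is logged alongside the numbers it
#' used, so the pass booleans are recomputable from the report itself.
#' Ineligible traits (fewer than `min_snps` instruments) are carried with
#' a status, never silently dropped.
#'
#' @param lib a [trait_library].
#' @param ld an [ld_matrix] used for clumping.
#' @param cfg a [screen_config()].
#' @return object of class `screen_report`: `table` (one row per trait
#'   with estimates, gate booleans and status), `final_causal_set`
#'   (replicated trait ids), `config`.
#' @export
run_mr_screen <- function(lib, ld, cfg = screen_config()) {
  if (!length(lib$traits)) {
    return(structure(list(table = data.frame(), final_causal_set = character(),
                          config = cfg),
                     class = "screen_report"))
  }
  rows <- lapply(names(lib$traits), function(id) {
    tr <- lib$traits[[id]]
    base <- data.frame(
      trait_id = id, cohort_tag = tr$cohort_tag,
      category = if (is.null(tr$category)) id else tr$category,
      status = "ok", k = NA_integer_,
      ivw_beta = NA_real_, ivw_se = NA_real_, ivw_pval = NA_real_,
      egger_beta = NA_real_, egger_pval = NA_real_,
      egger_intercept = NA_real_, egger_intercept_pval = NA_real_,
      wm_beta = NA_real_, wm_pval = NA_real_,
      Q = NA_real_, I2 = NA_real_, f_stat = NA_real_,
      steiger_ok = NA, no_single_driver = NA, seed = cfg$seed,
      stringsAsFactors = FALSE
    )
    sel <- select_instruments(tr$sumstats, cfg$p_thresh, cfg$min_snps)
    if (!sel$eligible) { base$status <- "ineligible (<min_snps instruments)"; return(base) }
    ins <- suppressWarnings(clump(sel$instruments, ld, cfg$clump_r2, cfg$clump_window_kb))
    if (nrow(ins) < cfg$min_snps) { base$status <- "ineligible after clumping"; return(base) }
    shared <- intersect(ins$variant_id, lib$outcome$data$variant_id)
    if (!length(shared)) { base$status <- "no shared variants"; return(base) }
    h <- tryCatch(
      harmonize(ins[ins$variant_id %in% shared, , drop = FALSE],
                lib$outcome$data[lib$outcome$data$variant_id %in% shared, , drop = FALSE],
                palindrome_maf_band = cfg$palindrome_maf_band,
                exposure_id = id, outcome_id = lib$outcome$trait_id,
                n_exp = mean(effective_n(tr$sumstats), na.rm = TRUE),
                n_out = mean(effective_n(lib$outcome), na.rm = TRUE)),
      error = function(e) NULL)
    if (is.null(h)) { base$status <- "no harmonizable instruments"; return(base) }
    bat <- mr_battery(h, n_boot = cfg$n_boot,
                      seed = derive_seed(cfg$seed, match(id, names(lib$traits))))
    base$k <- bat$k
    base$ivw_beta <- bat$ivw$beta; base$ivw_se <- bat$ivw$se
    base$ivw_pval <- bat$ivw$pval
    if (!is.null(bat$egger_slope)) {
      base$egger_beta <- bat$egger_slope$beta
      base$egger_pval <- bat$egger_slope$pval
      base$egger_intercept <- bat$egger_intercept$beta
      base$egger_intercept_pval <- bat$egger_intercept$pval
    }
    if (!is.null(bat$weighted_median)) {
      base$wm_beta <- bat$weighted_median$beta
      base$wm_pval <- bat$weighted_median$pval
    }
    if (!is.null(bat$het)) { base$Q <- bat$het$Q; base$I2 <- bat$het$I2 }
    base$f_stat <- as.numeric(bat$f_stat)
    if (!is.null(bat$steiger)) base$steiger_ok <- bat$steiger$direction_ok
    if (!is.null(bat$loo)) base$no_single_driver <- bat$loo$no_single_driver
    base
  })
  tab <- do.call(rbind, rows)

  tab$pass_phase1 <- !is.na(tab$ivw_pval) & tab$ivw_pval <= cfg$phase1_alpha
  tab$pass_sensitivity <- tab$pass_phase1 &
    !is.na(tab$egger_pval) & tab$egger_pval <= cfg$sensitivity_alpha &
    !is.na(tab$wm_pval) & tab$wm_pval <= cfg$sensitivity_alpha

  ## replication: a sign-concordant, sensitivity-passing hit in the other
  ## cohort class when a matched trait exists; with no counterpart the
  ## gate is vacuous under category-level matching
  match_key <- if (cfg$replication == "strict") tab$trait_id else tab$category
  tab$replicated <- vapply(seq_len(nrow(tab)), function(i) {
    if (!tab$pass_sensitivity[i]) return(FALSE)
    other <- which(match_key == match_key[i] &
                     tab$cohort_tag != tab$cohort_tag[i])
    if (!length(other)) return(cfg$replication == "category")
    any(tab$pass_sensitivity[other] &
          sign(tab$ivw_beta[other]) == sign(tab$ivw_beta[i]))
  }, logical(1))

  defined <- !is.na(tab$ivw_pval)
  tab$ivw_pval_bh <- NA_real_
  tab$ivw_pval_bh[defined] <- fdr_bh(tab$ivw_pval[defined], cfg$phase1_alpha)$adjusted

  structure(list(table = tab,
                 final_causal_set = sort(unique(tab$trait_id[tab$replicated])),
                 config = cfg),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d traits; %d pass phase I, %d pass sensitivity, %d replicated\n",
              nrow(x$table), sum(x$table$pass_phase1),
              sum(x$table$pass_sensitivity), sum(x$table$replicated)))
  if (length(x$final_causal_set)) {
    cat("final causal set:", paste(x$final_causal_set, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the LDSC genetic-correlation scan
#'
#' Estimates rg between each library trait and the outcome, applies the
#' heritability-bounds filter (default h2 in (0, 1\]), and controls FDR by
#' Benjamini-Hochberg across all traits with a defined rg (the FDR family
#' excludes failures; its size is recorded).
#'
#' @param traits named list; each element a list with `z` (z-scores
#'   aligned to `lds`) and `n` (sample size).
#' @param outcome list with `z` and `n` for the outcome trait.
#' @param lds an [ldscore_table].
#' @param cfg a [screen_config()].
#' @param n_blocks jackknife blocks.
#' @return object of class `ldsc_screen_report`: `table` (trait_id, h2,
#'   rg, rg_se, rg_pval, fdr_pval, significant, status), `family_size`.
#' @export
run_ldsc_screen <- function(traits, outcome, lds, cfg = screen_config(),
                            n_blocks = 200L) {
  rows <- lapply(names(traits), function(id) {
    tr <- traits[[id]]
    res <- ldsc_rg(tr$z, outcome$z, tr$n, outcome$n, lds, n_blocks)
    status <- "ok"
    if (!is.na(res$reason)) {
      status <- res$reason
    } else if (res$h2_1 <= cfg$h2_bounds[1] || res$h2_1 > cfg$h2_bounds[2]) {
      status <- "h2 outside bounds"
    }
    data.frame(trait_id = id, h2 = res$h2_1, h2_se = res$h2_1_se,
               rg = res$rg, rg_se = res$rg_se, rg_pval = res$rg_pval,
               bivariate_intercept = res$intercepts[["bivariate"]],
               status = status, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  in_family <- tab$status == "ok" & !is.na(tab$rg_pval)
  tab$fdr_pval <- NA_real_
  tab$significant <- FALSE
  if (any(in_family)) {
    adj <- fdr_bh(tab$rg_pval[in_family], cfg$fdr_alpha)
    tab$fdr_pval[in_family] <- adj$adjusted
    tab$significant[in_family] <- adj$significant
  }
  structure(list(table = tab, family_size = sum(in_family), config = cfg),
            class = "ldsc_screen_report")
}

#' @export
print.ldsc_screen_report <- function(x, ...) {
  cat(sprintf("<ldsc_screen_report> %d traits (FDR family %d); %d significant at FDR %.2f\n",
              nrow(x$table), x$family_size, sum(x$table$significant),
              x$config$fdr_alpha))
  invisible(x)
}

#' Write a screen report to TSV plus a JSON manifest
#'
#' One TSV per analysis table and a manifest recording thresholds, seeds
#' and package version for reproducibility.
#'
#' @param report a `screen_report` or `ldsc_screen_report`.
#' @param out_dir output directory (created if missing).
#' @param name file stem.
#' @return paths written, invisibly.
#' @export
write_screen_report <- function(report, out_dir, name = "screen") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(report$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    name = name,
    config = report$config,
    package_version = as.character(utils::packageVersion("mrscreen")),
    final_causal_set = report$final_causal_set,
    family_size = report$family_size,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  json <- file.path(out_dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, json, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(c(tsv, json))
}
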