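## GWAS summary-statistics container and I/O.
##
## A `sumstats` object is the shared data model for every downstream stage:
## one row per variant with alleles, frequency, effect size (log-odds for
## binary traits), standard error, p-value and per-row sample size.

#' Default column map for summary-statistics tables
#'
#' The de-facto GWAS dialect: SNP, CHR, BP, A1 (effect allele), A2,
#' FRQ/EAF, BETA, SE, P, N.
#'
#' @return named list mapping internal field names to candidate column names.
#' @export
default_column_map <- function() {
  list(
    variant_id    = c("SNP", "variant_id", "rsid", "ID"),
    chrom         = c("CHR", "chrom", "chromosome"),
    pos           = c("BP", "pos", "position"),
    effect_allele = c("A1", "effect_allele", "EA"),
    other_allele  = c("A2", "other_allele", "OA", "NEA"),
    eaf           = c("FRQ", "EAF", "eaf", "FREQ"),
    beta          = c("BETA", "beta", "b"),
    se            = c("SE", "se"),
    pval          = c("P", "pval", "p", "PVAL"),
    n             = c("N", "n")
  )
}

#' Construct a validated summary-statistics object
#'
#' Rows violating the per-variant invariants (se > 0, pval in (0, 1],
#' effect allele != other allele, eaf in \[0, 1\] or NA, exactly two alleles)
#' are dropped and tallied; duplicated variant ids keep the smallest p-value.
#' Alleles are upper-cased; indel allele strings are kept verbatim.
#'
#' @param records data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `chrom`, `pos`,
#'   `eaf`, `n`.
#' @param trait_id trait identifier string.
#' @param trait_type `"binary"` (betas on the log-odds scale) or
#'   `"quantitative"`.
#' @param n_cases,n_controls optional integer totals for binary traits.
#' @param metadata named character list (source, genome build; default
#'   build GRCh37 — coordinates are 1-based inclusive and the build is
#'   carried as metadata only).
#' @return object of class `sumstats`: list with `trait_id`, `trait_type`,
#'   `data` (one row per retained variant), `n_cases`, `n_controls`,
#'   `metadata`, and `dropped` (named tally of discarded rows).
#' @export
sumstats <- function(records, trait_id, trait_type = c("binary", "quantitative"),
                     n_cases = NA_integer_, n_controls = NA_integer_,
                     metadata = list()) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  for (col in mandatory) {
    if (!col %in% names(records)) {
      stop("missing mandatory column: ", col, call. = FALSE)
    }
  }
  d <- data.frame(
    variant_id    = as.character(records$variant_id),
    chrom         = if ("chrom" %in% names(records)) as.character(records$chrom) else NA_character_,
    pos           = if ("pos" %in% names(records)) as.integer(records$pos) else NA_integer_,
    effect_allele = toupper(as.character(records$effect_allele)),
    other_allele  = toupper(as.character(records$other_allele)),
    eaf           = if ("eaf" %in% names(records)) as.numeric(records$eaf) else NA_real_,
    beta          = as.numeric(records$beta),
    se            = as.numeric(records$se),
    pval          = as.numeric(records$pval),
    n             = if ("n" %in% names(records)) as.numeric(records$n) else NA_real_,
    stringsAsFactors = FALSE
  )

  dropped <- c(bad_se = 0L, bad_pval = 0L, bad_alleles = 0L, bad_eaf = 0L,
               multiallelic = 0L, duplicate = 0L)

  ok_se <- is.finite(d$se) & d$se > 0
  ok_p <- is.finite(d$pval) & d$pval > 0 & d$pval <= 1
  ok_beta <- is.finite(d$beta)
  base_ok <- is.finite(d$beta)
  valid_allele <- function(a) nzchar(a) & grepl("^[ACGT]+$", a)
  ## multi-allelic records (comma-separated allele lists) are rejected:
  ## exactly two alleles per record
  multi <- grepl(",", d$effect_allele) | grepl(",", d$other_allele)
  ok_al <- !multi & valid_allele(d$effect_allele) & valid_allele(d$other_allele) &
    d$effect_allele != d$other_allele
  ok_eaf <- is.na(d$eaf) | (d$eaf >= 0 & d$eaf <= 1)

  dropped["bad_se"] <- sum(!ok_se)
  dropped["bad_pval"] <- sum(ok_se & !ok_p)
  dropped["multiallelic"] <- sum(ok_se & ok_p & multi)
  dropped["bad_alleles"] <- sum(ok_se & ok_p & !multi & !ok_al)
  dropped["bad_eaf"] <- sum(ok_se & ok_p & ok_al & !ok_eaf)
  keep <- ok_se & ok_p & ok_al & ok_eaf & ok_beta & base_ok
  d <- d[keep, , drop = FALSE]

  if (anyDuplicated(d$variant_id)) {
    ord <- order(d$pval, seq_len(nrow(d)))
    d <- d[ord, , drop = FALSE]
    dup <- duplicated(d$variant_id)
    dropped["duplicate"] <- sum(dup)
    d <- d[!dup, , drop = FALSE]
    d <- d[order(match(d$variant_id, unique(d$variant_id))), , drop = FALSE]
  }
  rownames(d) <- NULL

  md <- utils::modifyList(list(build = "GRCh37"), as.list(metadata))
  structure(
    list(trait_id = trait_id, trait_type = trait_type, data = d,
         n_cases = n_cases, n_controls = n_controls,
         metadata = md, dropped = dropped),
    class = "sumstats"
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s): %d variants, %d dropped on read\n",
              x$trait_id, x$trait_type, nrow(x$data), sum(x$dropped)))
  invisible(x)
}

#' Number of variants in a sumstats object
#' @param x a `sumstats` object.
#' @return integer count.
#' @export
n_variants <- function(x) nrow(x$data)

resolve_columns <- function(header, column_map) {
  out <- list()
  for (field in names(column_map)) {
    hit <- intersect(column_map[[field]], header)
    out[[field]] <- if (length(hit)) hit[[1L]] else NA_character_
  }
  out
}

#' Read a GWAS summary-statistics table
#'
#' Reads a headered, tab- or whitespace-delimited table, maps columns via
#' `column_map`, validates each row and returns a [sumstats] object.
#' Invalid rows are dropped and tallied (see the `dropped` field); a missing
#' mandatory column is a hard error naming the column.
#'
#' @param path file path.
#' @param column_map as [default_column_map()]; each entry is a vector of
#'   acceptable header names tried in order.
#' @param trait_id trait identifier; defaults to the file base name.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param n_cases,n_controls,metadata passed to [sumstats()].
#' @return a `sumstats` object.
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          trait_id = NULL,
                          trait_type = c("binary", "quantitative"),
                          n_cases = NA_integer_, n_controls = NA_integer_,
                          metadata = list()) {
  trait_type <- match.arg(trait_type)
  if (is.null(trait_id)) trait_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           na.strings = c("NA", "", "."))
  cols <- resolve_columns(names(raw), column_map)
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  for (field in mandatory) {
    if (is.na(cols[[field]])) {
      stop("missing mandatory column for field '", field, "' (tried: ",
           paste(column_map[[field]], collapse = ", "), ")", call. = FALSE)
    }
  }
  rec <- data.frame(variant_id = raw[[cols$variant_id]], stringsAsFactors = FALSE)
  for (field in c("chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")) {
    if (!is.na(cols[[field]])) rec[[field]] <- raw[[cols[[field]]]]
  }
  md <- utils::modifyList(list(source = path), as.list(metadata))
  sumstats(rec, trait_id = trait_id, trait_type = trait_type,
           n_cases = n_cases, n_controls = n_controls, metadata = md)
}

#' Write a summary-statistics table
#'
#' Emits the same headered TSV dialect that [read_sumstats()] consumes
#' (SNP/CHR/BP/A1/A2/FRQ/BETA/SE/P/N); floats carry 10+ significant digits
#' so a read/write round trip is lossless for all retained fields.
#'
#' @param x a `sumstats` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  d <- x$data
  out <- data.frame(
    SNP = d$variant_id, CHR = d$chrom, BP = d$pos,
    A1 = d$effect_allele, A2 = d$other_allele,
    FRQ = format(d$eaf, digits = 12, trim = TRUE, scientific = FALSE),
    BETA = format(d$beta, digits = 12, trim = TRUE),
    SE = format(d$se, digits = 12, trim = TRUE),
    P = format(d$pval, digits = 12, trim = TRUE),
    N = d$n,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Intersect two summary-statistics panels on variant id
#'
#' Pairs are matched purely on `variant_id`, in the order of `a`; no allele
#' logic is applied here (harmonization is a separate step). An empty
#' intersection yields a zero-row result, not an error.
#'
#' @param a,b `sumstats` objects.
#' @return data.frame with the paired records; columns of `a` suffixed
#'   `_a`, of `b` suffixed `_b`, plus a leading `variant_id`.
#' @export
intersect_sumstats <- function(a, b) {
  ids <- a$data$variant_id[a$data$variant_id %in% b$data$variant_id]
  ia <- match(ids, a$data$variant_id)
  ib <- match(ids, b$data$variant_id)
  da <- a$data[ia, , drop = FALSE]
  db <- b$data[ib, , drop = FALSE]
  names(da) <- paste0(names(da), "_a")
  names(db) <- paste0(names(db), "_b")
  out <- cbind(variant_id = ids, da[-1], db[-1], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Effective per-variant sample size
#'
#' Per-row `n` takes precedence over the trait-level total (cases +
#' controls for binary traits).
#'
#' @param x a `sumstats` object.
#' @param default fallback when neither is available.
#' @return numeric vector, one entry per variant.
#' @export
effective_n <- function(x, default = NA_real_) {
  n <- x$data$n
  trait_n <- if (!is.na(x$n_cases) && !is.na(x$n_controls)) {
    x$n_cases + x$n_controls
  } else {
    default
  }
  n[is.na(n)] <- trait_n
  n
}
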