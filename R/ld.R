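## Signed LD correlation panel used for clumping and proxy lookup.

#' Construct an LD matrix object
#'
#' @param r square numeric matrix of signed LD correlations with unit
#'   diagonal, dimnames = variant ids.
#' @param positions data.frame with columns `variant_id`, `chrom`, `pos`.
#' @return object of class `ld_matrix`.
#' @export
ld_matrix <- function(r, positions) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (is.null(rownames(r))) stop("r must carry variant ids as dimnames")
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  if (max(abs(r)) > 1 + 1e-8) stop("|r| must be <= 1")
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(positions)))
  positions <- positions[match(rownames(r), positions$variant_id), , drop = FALSE]
  if (anyNA(positions$variant_id)) stop("positions missing for some LD panel variants")
  structure(list(variant_ids = rownames(r), r = r, positions = positions),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d variants\n", length(x$variant_ids)))
  invisible(x)
}

#' Signed LD correlation between two variants
#'
#' @param ld an `ld_matrix`.
#' @param id_a,id_b variant ids.
#' @return signed r, or `NA` if either variant is absent from the panel.
#' @export
ld_r <- function(ld, id_a, id_b) {
  ia <- match(id_a, ld$variant_ids)
  ib <- match(id_b, ld$variant_ids)
  if (is.na(ia) || is.na(ib)) return(NA_real_)
  ld$r[ia, ib]
}

#' Read an LD panel from text files
#'
#' Two dialects: a triplet list (`id_a`, `id_b`, `r`) or a square-matrix TSV
#' whose header row and first column are variant ids. Either way a panel
#' table (`variant_id`, `chrom`, `pos`) supplies coordinates. Missing
#' triplet pairs default to r = 0; the diagonal is forced to 1.
#'
#' @param path LD file path.
#' @param panel_path panel table path.
#' @param format `"triplet"` or `"square"`.
#' @return an `ld_matrix`.
#' @export
read_ld_matrix <- function(path, panel_path, format = c("triplet", "square")) {
  format <- match.arg(format)
  panel <- data.table::fread(panel_path, header = TRUE, data.table = FALSE)
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(panel)))
  ids <- as.character(panel$variant_id)
  if (format == "triplet") {
    tri <- data.table::fread(path, header = TRUE, data.table = FALSE)
    stopifnot(all(c("id_a", "id_b", "r") %in% names(tri)))
    r <- diag(1, length(ids))
    dimnames(r) <- list(ids, ids)
    ia <- match(as.character(tri$id_a), ids)
    ib <- match(as.character(tri$id_b), ids)
    keep <- !is.na(ia) & !is.na(ib)
    r[cbind(ia[keep], ib[keep])] <- tri$r[keep]
    r[cbind(ib[keep], ia[keep])] <- tri$r[keep]
    diag(r) <- 1
  } else {
    sq <- data.table::fread(path, header = TRUE, data.table = FALSE)
    rn <- as.character(sq[[1L]])
    r <- as.matrix(sq[, -1L, drop = FALSE])
    dimnames(r) <- list(rn, colnames(r))
    r <- r[ids, ids, drop = FALSE]
  }
  ld_matrix(r, panel)
}

#' Block-diagonal LD matrix with constant within-block correlation
#'
#' Convenience constructor used by the synthetic-data generators: variants
#' are laid out along one or more chromosomes in blocks of `block_size`
#' with pairwise correlation `rho` inside a block and 0 between blocks.
#'
#' @param m number of variants.
#' @param block_size variants per LD block.
#' @param rho within-block signed correlation.
#' @param chrom chromosome label(s) recycled across blocks.
#' @param spacing_bp base pairs between adjacent variants.
#' @param prefix variant-id prefix.
#' @return an `ld_matrix`.
#' @export
block_ld_matrix <- function(m, block_size = 10, rho = 0.5, chrom = "1",
                            spacing_bp = 5000L, prefix = "rs") {
  ids <- paste0(prefix, seq_len(m))
  r <- diag(1, m)
  block <- (seq_len(m) - 1L) %/% block_size
  for (b in unique(block)) {
    idx <- which(block == b)
    r[idx, idx] <- rho
  }
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  positions <- data.frame(variant_id = ids,
                          chrom = rep_len(chrom, m),
                          pos = seq_len(m) * spacing_bp,
                          stringsAsFactors = FALSE)
  ld_matrix(r, positions)
}
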