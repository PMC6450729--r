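# Independent brute-force oracles used to check the package's estimators.
# These are written from the definitions, not by calling package internals,
# and stay deliberately loop-based and naive.

oracle_ivw <- function(beta_exp, beta_out, se_out) {
  k <- length(beta_exp)
  ratios <- numeric(k); weights <- numeric(k)
  for (i in seq_len(k)) {
    ratios[i] <- beta_out[i] / beta_exp[i]
    weights[i] <- beta_exp[i]^2 / se_out[i]^2
  }
  est <- sum(weights * ratios) / sum(weights)
  Q <- 0
  for (i in seq_len(k)) Q <- Q + weights[i] * (ratios[i] - est)^2
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  se_fixed <- sqrt(1 / sum(weights))
  se_re <- if (k > 1) se_fixed * max(1, sqrt(Q / (k - 1))) else se_fixed
  list(beta = est, Q = Q, I2 = I2, se_fixed = se_fixed, se_re = se_re)
}

oracle_weighted_median <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]; w <- weights[ord] / sum(weights)
  s <- numeric(length(w))
  acc <- 0
  for (i in seq_along(w)) { s[i] <- acc + w[i] / 2; acc <- acc + w[i] }
  if (0.5 <= s[1]) return(v[1])
  if (0.5 >= s[length(s)]) return(v[length(v)])
  for (i in 2:length(s)) {
    if (s[i] >= 0.5) {
      return(v[i - 1] + (v[i] - v[i - 1]) * (0.5 - s[i - 1]) / (s[i] - s[i - 1]))
    }
  }
}

# p-value-priority clumping reference: repeatedly take the smallest p
# (ties by id) from the remaining pool and delete its window conflicts
oracle_clump_ids <- function(df, rmat, r2_thresh, window_bp) {
  pool <- df
  kept <- character()
  while (nrow(pool)) {
    ord <- order(pool$pval, pool$variant_id)
    best <- pool[ord[1], ]
    kept <- c(kept, best$variant_id)
    drop <- rep(FALSE, nrow(pool))
    for (i in seq_len(nrow(pool))) {
      if (pool$variant_id[i] == best$variant_id) { drop[i] <- TRUE; next }
      if (pool$chrom[i] == best$chrom &&
          abs(pool$pos[i] - best$pos) <= window_bp &&
          rmat[best$variant_id, pool$variant_id[i]]^2 >= r2_thresh) {
        drop[i] <- TRUE
      }
    }
    pool <- pool[!drop, , drop = FALSE]
  }
  sort(kept)
}

# enumeration oracle for colocalization: sum priors x Bayes factors over
# every per-variant causal configuration (single causal per trait)
oracle_coloc <- function(beta1, se1, beta2, se2, sd1, sd2,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  abf <- function(b, s, w) {
    r <- w^2 / (s^2 + w^2)
    sqrt(1 - r) * exp(0.5 * (b / s)^2 * r)
  }
  k <- length(beta1)
  bf1 <- vapply(seq_len(k), function(i) abf(beta1[i], se1[i], sd1), 1)
  bf2 <- vapply(seq_len(k), function(i) abf(beta2[i], se2[i], sd2), 1)
  m <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (i in seq_len(k)) m["H1"] <- m["H1"] + p1 * bf1[i]
  for (j in seq_len(k)) m["H2"] <- m["H2"] + p2 * bf2[j]
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) m["H3"] <- m["H3"] + p1 * p2 * bf1[i] * bf2[j]
  }
  for (i in seq_len(k)) m["H4"] <- m["H4"] + p12 * bf1[i] * bf2[i]
  m / sum(m)
}

# quick harmonized set with well-behaved SEs
make_hset <- function(beta_exp, beta_out, se_out, se_exp = NULL, ...) {
  k <- length(beta_exp)
  if (is.null(se_exp)) se_exp <- rep(0.01, k)
  harmonized_set(paste0("v", seq_len(k)), beta_exp, se_exp, beta_out, se_out, ...)
}

# draw a harmonized set directly from the two-sample model (fast path for
# property tests that do not need the full panel generator)
draw_hset <- function(k, theta, se_exp = 0.01, se_out = 0.02,
                      beta_sd = 0.1, pleio = rep(0, k)) {
  bx <- stats::rnorm(k, 0, beta_sd)
  bx <- sign(bx) * pmax(abs(bx), 3.5 * se_exp)   # keep instruments relevant
  bhat_x <- stats::rnorm(k, bx, se_exp)
  bhat_y <- stats::rnorm(k, theta * bx + pleio, se_out)
  make_hset(bhat_x, bhat_y, rep(se_out, k), rep(se_exp, k))
}

# block-diagonal merge of per-trait LD matrices (used by screen tests)
merge_ld <- function(lds) {
  ids <- unlist(lapply(lds, function(l) l$variant_ids))
  n <- length(ids)
  r <- diag(1, n)
  off <- 0L
  pos <- do.call(rbind, lapply(lds, function(l) l$positions))
  for (l in lds) {
    m <- length(l$variant_ids)
    r[off + seq_len(m), off + seq_len(m)] <- l$r
    off <- off + m
  }
  dimnames(r) <- list(ids, ids)
  ld_matrix(r, pos)
}

# give every variant of one simulated trait a unique id prefix so panels
# from several traits can coexist in one outcome / one merged LD matrix
relabel_sim <- function(sim, prefix) {
  swap <- function(ids) paste0(prefix, "_", ids)
  sim$exposure$data$variant_id <- swap(sim$exposure$data$variant_id)
  sim$outcome$data$variant_id <- swap(sim$outcome$data$variant_id)
  dimnames(sim$ld$r) <- list(swap(rownames(sim$ld$r)), swap(colnames(sim$ld$r)))
  sim$ld$variant_ids <- swap(sim$ld$variant_ids)
  sim$ld$positions$variant_id <- swap(sim$ld$positions$variant_id)
  sim$truth$instrument_ids <- swap(sim$truth$instrument_ids)
  sim
}

# small two-cohort library: each category simulated once per cohort with its
# own variant panel; the outcome concatenates every panel's outcome records
build_library <- function(seed, n_null_cat = 3, n_causal_cat = 1,
                          theta = 0.5) {
  traits <- list()
  lds <- list()
  out_records <- list()
  i <- 0L
  for (cat in seq_len(n_null_cat + n_causal_cat)) {
    causal <- cat <= n_causal_cat
    for (tag in c("published", "ukbb")) {
      i <- i + 1L
      sim <- simulate_two_sample(sim_config(
        seed = derive_seed_for_tests(seed, i),
        m_variants = 200, ld_block_size = 10, k_instruments = 20,
        h2_exposure = 0.1, n_exp = 5e4, n_out = 5e4,
        theta = if (causal) theta else 0))
      sim <- relabel_sim(sim, sprintf("c%d%s", cat, substr(tag, 1, 1)))
      id <- sprintf("%s_trait%d_%s", if (causal) "causal" else "null", cat, tag)
      traits[[id]] <- list(sumstats = sim$exposure, cohort_tag = tag,
                           category = paste0("cat", cat))
      lds[[id]] <- sim$ld
      out_records[[id]] <- sim$outcome$data
    }
  }
  outcome <- sumstats(do.call(rbind, out_records), "als", "binary",
                      n_cases = 15000L, n_controls = 35000L)
  list(lib = trait_library(traits, outcome), ld = merge_ld(lds))
}

derive_seed_for_tests <- function(seed, i) (seed * 1000L + i) %% 2147480000L

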