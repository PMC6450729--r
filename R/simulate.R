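## Synthetic-data generators with recorded ground truth, so every pipeline
## stage is testable at desk scale without external downloads. Summary
## statistics are drawn directly from their asymptotic sampling
## distributions (genotype-free); an optional genotype-level generator
## backs the risk-score module with real dosage matrices at small n.
##
## Every generator is a pure function of its configuration (which carries
## the seed); sub-streams are derived deterministically per component.

#' Simulation configuration
#'
#' Collects every knob of the generators with field-level validation.
#' Defaults describe a well-powered two-sample design: 50 true instruments
#' explaining 10% of exposure variance in a 100k-sample exposure GWAS,
#' a 100k-sample 30%-case outcome GWAS, block LD of 10 variants at
#' r = 0.5, and no pleiotropy or sample overlap unless requested.
#'
#' @param seed master RNG seed.
#' @param m_variants total variants simulated.
#' @param ld_block_size,ld_rho LD-block structure (constant within-block
#'   signed correlation).
#' @param maf_range uniform range for minor-allele frequencies.
#' @param k_instruments number of true instruments.
#' @param h2_exposure exposure variance explained by the instruments
#'   jointly (effect sizes are scaled to hit it exactly).
#' @param n_exp exposure GWAS sample size.
#' @param theta true causal effect of exposure on outcome.
#' @param pleiotropy `"none"`, `"balanced"` (zero-mean direct effects) or
#'   `"directional"` (mean `pleio_mean`).
#' @param pleio_mean,pleio_sd direct-effect distribution for pleiotropic
#'   instruments.
#' @param pleio_frac fraction of instruments given direct effects (default
#'   all, so the directional mean is the Egger intercept estimand; 0.4
#'   models a 40%-invalid instrument set).
#' @param overlap_frac fraction of shared samples between the studies
#'   (induces correlated estimation noise with correlation
#'   `overlap_frac * rho_pheno`).
#' @param rho_pheno phenotypic correlation among overlapping samples.
#' @param n_out outcome GWAS sample size.
#' @param case_fraction outcome case fraction (binary outcome on the
#'   log-odds scale).
#' @param M,h2_1,h2_2,rg LDSC-mode parameters: reference-panel size,
#'   heritability pair and genetic correlation.
#' @param mean_ldscore mean of the fabricated LD-score distribution.
#' @param coloc_mode `"shared"`, `"distinct"`, `"trait1"`, `"trait2"` or
#'   `"none"` causal architecture for a colocalization region.
#' @param coloc_effect causal standardized effect size in coloc mode.
#' @param n1,n2 per-trait sample sizes for LDSC/coloc modes.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, m_variants = 500L, ld_block_size = 10L,
                       ld_rho = 0.5, maf_range = c(0.05, 0.5),
                       k_instruments = 50L, h2_exposure = 0.1, n_exp = 1e5,
                       theta = 0, pleiotropy = c("none", "balanced", "directional"),
                       pleio_mean = 0.05, pleio_sd = 0.02, pleio_frac = 1,
                       overlap_frac = 0, rho_pheno = 0.5,
                       n_out = 1e5, case_fraction = 0.3,
                       M = 20000, h2_1 = 0.25, h2_2 = 0.25, rg = 0,
                       mean_ldscore = 10, coloc_mode = "shared",
                       coloc_effect = 0.05, n1 = 1e5, n2 = 1e5) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(m_variants > 0, k_instruments <= m_variants,
            h2_exposure >= 0, h2_exposure <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            overlap_frac >= 0, overlap_frac <= 1,
            case_fraction > 0, case_fraction < 1,
            n_exp > 0, n_out > 0, abs(rg) <= 1,
            abs(ld_rho) < 1, pleio_frac >= 0, pleio_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

## equicorrelated-block helpers: exact draws and products without a
## Cholesky factor (x_i = sqrt(rho) u_block + sqrt(1-rho) z_i)
block_noise <- function(m, block, rho) {
  u <- stats::rnorm(max(block))
  sqrt(rho) * u[block] + sqrt(1 - rho) * stats::rnorm(m)
}
block_mult <- function(beta, block, rho) {
  bs <- tapply(beta, block, sum)[as.character(block)]
  (1 - rho) * beta + rho * as.numeric(bs)
}

non_palindromic_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                  "G", "A", "C", "A", "G", "T", "C", "T"),
                                ncol = 2, byrow = TRUE)

#' Simulate a paired exposure/outcome two-sample MR data set
#'
#' Instruments affect the exposure; the outcome's per-variant effect is
#' `theta * beta_exp + pleiotropy + noise`, with sampling noise matching
#' each study's size and allele frequency, LD-block-correlated across
#' variants, and (optionally) correlated between studies through sample
#' overlap. Roughly 30% of outcome records have their allele order
#' swapped and 20% are strand-complemented so the harmonization step is
#' exercised end-to-end; allele pairs are non-palindromic by construction.
#'
#' @param cfg a [sim_config()].
#' @return list with `exposure` and `outcome` ([sumstats]), `ld` (an
#'   [ld_matrix]) and `truth` (a ledger: theta, pleiotropy model, true
#'   instrument ids, seed).
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, 1L))

  m <- cfg$m_variants
  block <- (seq_len(m) - 1L) %/% cfg$ld_block_size + 1L
  if (cfg$k_instruments > max(block)) {
    stop("infeasible design: more instruments than LD blocks", call. = FALSE)
  }
  if (cfg$h2_exposure > 0 && cfg$k_instruments == 0) {
    stop("infeasible design: h2_exposure > 0 with no instruments", call. = FALSE)
  }
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  ids <- sprintf("rs%06d", seq_len(m))

  ## one true instrument per block (at most) so clumping keeps them all
  inst_blocks <- sample(unique(block), cfg$k_instruments)
  inst_idx <- vapply(inst_blocks, function(b) {
    cand <- which(block == b)
    cand[1 + (b %% length(cand))]
  }, integer(1))
  beta <- numeric(m)
  if (cfg$k_instruments > 0 && cfg$h2_exposure > 0) {
    raw <- stats::rnorm(cfg$k_instruments)
    varg <- 2 * maf[inst_idx] * (1 - maf[inst_idx])
    beta[inst_idx] <- raw * sqrt(cfg$h2_exposure / sum(varg * raw^2))
  }

  se_exp <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exp)
  phi <- cfg$case_fraction
  se_out <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_out * phi * (1 - phi))

  ## direct effects are oriented relative to the exposure-increasing allele,
  ## so "directional" pleiotropy survives the Egger re-orientation step and
  ## its mean is the intercept estimand
  pleio <- numeric(m)
  if (cfg$pleiotropy != "none" && cfg$pleio_frac > 0 && cfg$k_instruments > 0) {
    if (cfg$pleio_frac >= 1) {
      tgt <- inst_idx
    } else {
      ## "pleio_frac invalid by weight": instrument IVW weight is
      ## proportional to its exposure-variance share, so accumulate
      ## randomly-ordered instruments until that share reaches the cap
      share <- 2 * maf[inst_idx] * (1 - maf[inst_idx]) * beta[inst_idx]^2
      share <- share / sum(share)
      ord <- sample(length(inst_idx))
      take <- ord[cumsum(share[ord]) <= cfg$pleio_frac]
      if (!length(take)) take <- ord[1]
      tgt <- inst_idx[take]
    }
    mu <- if (cfg$pleiotropy == "directional") cfg$pleio_mean else 0
    pleio[tgt] <- sign(beta[tgt]) * stats::rnorm(length(tgt), mu, cfg$pleio_sd)
  }

  mu_exp <- block_mult(beta, block, cfg$ld_rho)
  mu_out <- block_mult(cfg$theta * beta + pleio, block, cfg$ld_rho)

  z1 <- block_noise(m, block, cfg$ld_rho)
  z2r <- block_noise(m, block, cfg$ld_rho)
  rho_noise <- cfg$overlap_frac * cfg$rho_pheno
  z2 <- rho_noise * z1 + sqrt(1 - rho_noise^2) * z2r
  bhat_exp <- mu_exp + se_exp * z1
  bhat_out <- mu_out + se_out * z2

  al <- non_palindromic_pairs[sample(nrow(non_palindromic_pairs), m, TRUE), ,
                              drop = FALSE]
  chrom <- as.character((block - 1L) %% 22L + 1L)
  pos <- (seq_len(m) - 1L) %% cfg$ld_block_size * 5000L +
    ((block - 1L) %/% 22L) * 10^7 + 10^6

  ## p-values floored at the smallest normal double: z ~ 40 underflows the
  ## normal tail, and the data contract requires p > 0
  pfloor <- function(z) pmax(pval_norm(z), 1e-300)
  rec_exp <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                        effect_allele = al[, 1], other_allele = al[, 2],
                        eaf = maf, beta = bhat_exp, se = se_exp,
                        pval = pfloor(bhat_exp / se_exp), n = cfg$n_exp,
                        stringsAsFactors = FALSE)

  rec_out <- rec_exp
  rec_out$beta <- bhat_out
  rec_out$se <- se_out
  rec_out$pval <- pfloor(bhat_out / se_out)
  rec_out$n <- cfg$n_out
  swap <- stats::runif(m) < 0.3
  rec_out$effect_allele[swap] <- al[swap, 2]
  rec_out$other_allele[swap] <- al[swap, 1]
  rec_out$beta[swap] <- -rec_out$beta[swap]
  rec_out$eaf[swap] <- 1 - rec_out$eaf[swap]
  flip <- stats::runif(m) < 0.2
  rec_out$effect_allele[flip] <- complement_alleles(rec_out$effect_allele[flip])
  rec_out$other_allele[flip] <- complement_alleles(rec_out$other_allele[flip])

  r <- diag(1, m)
  for (b in unique(block)) {
    idx <- which(block == b)
    r[idx, idx] <- cfg$ld_rho
  }
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  ld <- ld_matrix(r, data.frame(variant_id = ids, chrom = chrom, pos = pos,
                                stringsAsFactors = FALSE))

  truth <- list(theta = cfg$theta, pleiotropy = cfg$pleiotropy,
                pleio_mean = if (cfg$pleiotropy == "directional") cfg$pleio_mean else 0,
                instrument_ids = ids[inst_idx], true_beta = beta[inst_idx],
                seed = cfg$seed)
  list(
    exposure = sumstats(rec_exp, "sim_exposure", "quantitative",
                        metadata = list(source = "synthetic")),
    outcome = sumstats(rec_out, "sim_outcome", "binary",
                       n_cases = round(cfg$n_out * phi),
                       n_controls = round(cfg$n_out * (1 - phi)),
                       metadata = list(source = "synthetic")),
    ld = ld, truth = truth
  )
}

#' Simulate paired z-scores under the bivariate LDSC model
#'
#' Fabricates LD scores (1 + gamma-distributed tail) and draws per-variant
#' z-score pairs from `E[z1^2] = 1 + n1 h2_1 l / M`,
#' `E[z1 z2] = sqrt(n1 n2) rg sqrt(h2_1 h2_2) l / M + c`, where the
#' cross-intercept `c = overlap_frac * rho_pheno` models sample overlap.
#'
#' @param cfg a [sim_config()] (fields `m_variants`, `M`, `h2_1`, `h2_2`,
#'   `rg`, `n1`, `n2`, `overlap_frac`, `rho_pheno`, `mean_ldscore`).
#' @return list with `z1`, `z2`, `n1`, `n2`, `lds` (an [ldscore_table])
#'   and `truth`.
#' @export
simulate_ldsc <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, 2L))

  m <- cfg$m_variants
  l <- 1 + stats::rgamma(m, shape = 2, scale = (cfg$mean_ldscore - 1) / 2)
  gencov <- cfg$rg * sqrt(cfg$h2_1 * cfg$h2_2)
  c_int <- cfg$overlap_frac * cfg$rho_pheno
  v1 <- 1 + cfg$n1 * cfg$h2_1 * l / cfg$M
  v2 <- 1 + cfg$n2 * cfg$h2_2 * l / cfg$M
  cv <- sqrt(cfg$n1 * cfg$n2) * gencov * l / cfg$M + c_int
  cv <- sign(cv) * pmin(abs(cv), 0.999 * sqrt(v1 * v2))  # keep each Sigma PD
  z1 <- sqrt(v1) * stats::rnorm(m)
  rho <- cv / sqrt(v1 * v2)
  z2 <- sqrt(v2) * (rho * z1 / sqrt(v1) + sqrt(1 - rho^2) * stats::rnorm(m))

  lds <- ldscore_table(sprintf("rs%06d", seq_len(m)),
                       chrom = rep("1", m), pos = seq_len(m) * 1000L,
                       ldscore = l, M = cfg$M)
  truth <- list(h2_1 = cfg$h2_1, h2_2 = cfg$h2_2, rg = cfg$rg,
                gencov = gencov, cross_intercept = c_int, seed = cfg$seed)
  list(z1 = z1, z2 = z2, n1 = cfg$n1, n2 = cfg$n2, lds = lds, truth = truth)
}

#' Simulate a colocalization region panel
#'
#' One region of `m_variants` with equicorrelated LD blocks and a
#' configurable causal architecture: a shared causal variant, two distinct
#' causal variants in different blocks, a single-trait causal, or none.
#' Marginal effects are `R beta_joint`; estimates add LD-correlated noise
#' at `se = 1/sqrt(n)` (standardized scale).
#'
#' @param cfg a [sim_config()] (fields `m_variants`, `ld_block_size`,
#'   `ld_rho`, `coloc_mode`, `coloc_effect`, `n1`, `n2`).
#' @return list with `panel` (a [region_panel]) and `truth` (causal
#'   variant ids per trait).
#' @export
simulate_coloc_region <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, 3L))

  m <- cfg$m_variants
  block <- (seq_len(m) - 1L) %/% cfg$ld_block_size + 1L
  ids <- sprintf("rs%06d", seq_len(m))
  b1 <- numeric(m); b2 <- numeric(m)
  mode <- cfg$coloc_mode
  cv1 <- cv2 <- NA_character_
  if (mode == "shared") {
    c1 <- sample(m, 1)
    b1[c1] <- cfg$coloc_effect; b2[c1] <- cfg$coloc_effect
    cv1 <- cv2 <- ids[c1]
  } else if (mode == "distinct") {
    blocks <- sample(unique(block), 2)
    c1 <- which(block == blocks[1])[1]
    c2 <- which(block == blocks[2])[1]
    b1[c1] <- cfg$coloc_effect; b2[c2] <- cfg$coloc_effect
    cv1 <- ids[c1]; cv2 <- ids[c2]
  } else if (mode == "trait1") {
    c1 <- sample(m, 1); b1[c1] <- cfg$coloc_effect; cv1 <- ids[c1]
  } else if (mode == "trait2") {
    c2 <- sample(m, 1); b2[c2] <- cfg$coloc_effect; cv2 <- ids[c2]
  } else if (mode != "none") {
    stop("unknown coloc_mode: ", mode)
  }

  se1 <- rep(1 / sqrt(cfg$n1), m)
  se2 <- rep(1 / sqrt(cfg$n2), m)
  bhat1 <- block_mult(b1, block, cfg$ld_rho) + se1 * block_noise(m, block, cfg$ld_rho)
  bhat2 <- block_mult(b2, block, cfg$ld_rho) + se2 * block_noise(m, block, cfg$ld_rho)

  panel <- region_panel(
    region_id = sprintf("region_seed%d", cfg$seed),
    variant_id = ids, beta1 = bhat1, se1 = se1, beta2 = bhat2, se2 = se2,
    chrom = "1", start = 1L, end = m * 1000L,
    type1 = "quantitative", type2 = "binary"
  )
  list(panel = panel,
       truth = list(mode = mode, causal_trait1 = cv1, causal_trait2 = cv2,
                    seed = cfg$seed))
}

#' Simulate an individual-level cohort for risk-score analysis
#'
#' Genotype dosages are binomial(2, maf); disease liability is logistic in
#' the weighted score plus sex/age/PC covariate effects. Strata labels
#' (carrier, familial, sporadic, male, female) are assigned so subgroup
#' reruns are exercised.
#'
#' @param n_samples cohort size.
#' @param k_variants scored variants.
#' @param score_logor log-odds-ratio per SD of the standardized score
#'   (0 for a null cohort).
#' @param base_rate intercept-scale case probability.
#' @param maf_range allele-frequency range.
#' @param seed RNG seed.
#' @return list with `cohort` (a [cohort_matrix]), `weights` (named
#'   vector used to build the liability) and `truth`.
#' @export
simulate_grs_cohort <- function(n_samples = 2000L, k_variants = 20L,
                                score_logor = 0.3, base_rate = 0.3,
                                maf_range = c(0.1, 0.5), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 4L))

  maf <- stats::runif(k_variants, maf_range[1], maf_range[2])
  ids <- sprintf("grs%03d", seq_len(k_variants))
  D <- vapply(maf, function(p) stats::rbinom(n_samples, 2L, p), numeric(n_samples))
  colnames(D) <- ids
  weights <- stats::rnorm(k_variants, 0, 0.1)
  names(weights) <- ids
  raw_score <- drop(D %*% weights)
  zscore <- (raw_score - mean(raw_score)) / stats::sd(raw_score)
  sex <- stats::rbinom(n_samples, 1, 0.5)
  age <- stats::rnorm(n_samples, 60, 10)
  pcs <- matrix(stats::rnorm(n_samples * 20), n_samples)
  colnames(pcs) <- paste0("PC", 1:20)
  eta <- stats::qlogis(base_rate) + score_logor * zscore +
    0.1 * sex + 0.01 * (age - 60) + drop(pcs[, 1] * 0.05)
  y <- stats::rbinom(n_samples, 1, stats::plogis(eta))

  fam <- stats::runif(n_samples) < 0.1
  strata <- list(
    c9orf72_carrier = stats::runif(n_samples) < 0.08,
    familial = fam,
    sporadic = !fam,
    male = sex == 1,
    female = sex == 0
  )
  cohort <- cohort_matrix(sprintf("s%05d", seq_len(n_samples)), D, y,
                          covariates = data.frame(sex = sex, age = age, pcs),
                          strata = strata)
  list(cohort = cohort, weights = weights,
       truth = list(score_logor = score_logor, base_rate = base_rate,
                    seed = seed))
}
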