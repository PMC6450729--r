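rec <- function(id, ea, oa, beta, se = 0.02, pval = 1e-9, eaf = 0.3,
                chrom = "1", pos = 1000L) {
  data.frame(variant_id = id, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se, pval = pval,
             stringsAsFactors = FALSE)
}

test_that("instrument selection applies the threshold and eligibility flag", {
  d <- do.call(rbind, c(
    lapply(1:3, function(i) rec(paste0("hit", i), "A", "G", 0.1, pval = 1e-9)),
    lapply(1:100, function(i) rec(paste0("bg", i), "A", "G", 0.01, pval = 1e-4))
  ))
  ss <- sumstats(d, "exp", "quantitative")
  sel <- select_instruments(ss)
  expect_equal(sel$n, 3L)
  expect_true(sel$eligible)
  expect_setequal(sel$instruments$variant_id, paste0("hit", 1:3))

  one <- sumstats(d[c(1, 4:10), ], "exp", "quantitative")
  expect_false(select_instruments(one)$eligible)   # one hit: ineligible status
  expect_equal(select_instruments(ss, p_thresh = 1)$n, 103L)
})

test_that("clumping keeps the better p in LD, respects chromosomes and windows", {
  ids <- c("a", "b")
  r <- matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2, dimnames = list(ids, ids))
  ld <- ld_matrix(r, data.frame(variant_id = ids, chrom = "1",
                                pos = c(1000L, 2000L)))
  d <- rbind(rec("a", "A", "G", 0.1, pval = 1e-10, pos = 1000L),
             rec("b", "A", "G", 0.1, pval = 1e-8, pos = 2000L))
  expect_equal(clump(d, ld)$variant_id, "a")

  ld2 <- ld_matrix(matrix(c(1, 0.995, 0.995, 1), 2, dimnames = list(ids, ids)),
                   data.frame(variant_id = ids, chrom = c("1", "2"),
                              pos = c(1000L, 1000L)))
  d2 <- rbind(rec("a", "A", "G", 0.1, pval = 1e-10, chrom = "1"),
              rec("b", "A", "G", 0.1, pval = 1e-8, chrom = "2"))
  expect_equal(nrow(clump(d2, ld2)), 2L)          # window is intra-chromosomal

  ids5 <- paste0("v", 1:5)
  r5 <- diag(1, 5)
  dimnames(r5) <- list(ids5, ids5)
  ld5 <- ld_matrix(r5,
                   data.frame(variant_id = ids5, chrom = "1",
                              pos = seq(1000L, 5000L, 1000L)))
  d5 <- do.call(rbind, lapply(1:5, function(i)
    rec(ids5[i], "A", "G", 0.1, pval = 10^-(8 + i), pos = i * 1000L)))
  expect_equal(nrow(clump(d5, ld5)), 5L)
  expect_error(clump(d5, ld5, r2_thresh = 0), "r2_thresh")
})

test_that("clumping is input-order invariant and matches the reference oracle", {
  set.seed(42)
  for (rep in 1:12) {
    m <- sample(4:12, 1)
    ids <- paste0("s", sample(100, m))
    A <- matrix(rnorm(m * m), m)
    r <- cov2cor(crossprod(A) + diag(m))
    dimnames(r) <- list(ids, ids)
    pos <- data.frame(variant_id = ids, chrom = sample(c("1", "2"), m, TRUE),
                      pos = sample.int(2e7, m))
    ld <- ld_matrix(r, pos)
    d <- do.call(rbind, lapply(seq_len(m), function(i)
      rec(ids[i], "A", "G", 0.1, pval = runif(1, 1e-12, 1e-6),
          chrom = pos$chrom[i], pos = pos$pos[i])))
    got <- clump(d, ld, r2_thresh = 0.1, window_kb = 10000L)
    shuffled <- clump(d[sample(m), ], ld, r2_thresh = 0.1, window_kb = 10000L)
    expect_equal(got$variant_id, shuffled$variant_id)
    expect_equal(sort(got$variant_id),
                 oracle_clump_ids(d, r, 0.1, 10000 * 1000))
  }
})

test_that("proxy lookup picks the best qualifying proxy and reports its sign", {
  ids <- c("x", "p1", "p2")
  r <- diag(1, 3)
  r[1, 2] <- r[2, 1] <- sqrt(0.95)
  r[1, 3] <- r[3, 1] <- -sqrt(0.85)
  dimnames(r) <- list(ids, ids)
  ld <- ld_matrix(r, data.frame(variant_id = ids, chrom = "1",
                                pos = c(1L, 2L, 3L)))
  out <- sumstats(rbind(rec("p1", "A", "G", 0.05),
                        rec("p2", "T", "C", -0.04)), "out", "binary")
  hit <- proxy_lookup("x", out, ld)
  expect_equal(hit$proxy_id, "p1")
  expect_gt(hit$r, 0)

  ## only the negative-r proxy available: caller must re-sign the exposure
  out2 <- sumstats(rec("p2", "T", "C", -0.04), "out", "binary")
  hit2 <- proxy_lookup("x", out2, ld)
  expect_equal(hit2$proxy_id, "p2")
  expect_lt(hit2$r, 0)
  expect_null(proxy_lookup("x", out2, ld, r2_min = 0.9))  # below threshold
})

test_that("harmonization handles orientation, swaps, strand flips, palindromes", {
  e <- rbind(rec("v1", "A", "G", 0.10, eaf = 0.2),
             rec("v2", "A", "G", 0.20, eaf = 0.2),
             rec("v3", "A", "G", 0.15, eaf = 0.2),
             rec("v4", "A", "T", 0.12, eaf = 0.50),
             rec("v5", "A", "T", 0.12, eaf = 0.10),
             rec("v6", "C", "G", 0.08, eaf = 0.90),
             rec("v7", "A", "G", 0.05, eaf = 0.2))
  o <- rbind(rec("v1", "A", "G", 0.05),                 # same orientation
             rec("v2", "G", "A", 0.05, eaf = 0.7),      # swapped alleles
             rec("v3", "T", "C", 0.07, eaf = 0.2),      # strand complement
             rec("v4", "A", "T", 0.03, eaf = 0.50),     # ambiguous palindrome
             rec("v5", "A", "T", 0.03, eaf = 0.88),     # palindrome, flipped strand
             rec("v6", "C", "G", 0.04, eaf = 0.91),     # palindrome, agrees
             rec("v7", "A", "C", 0.05))                 # incompatible alleles
  h <- suppressWarnings(harmonize(e, o))
  expect_setequal(h$variant_ids, c("v1", "v2", "v3", "v5", "v6"))
  expect_equal(h$beta_out[h$variant_ids == "v1"], 0.05)
  expect_equal(h$beta_out[h$variant_ids == "v2"], -0.05)  # swap negates
  expect_equal(h$beta_out[h$variant_ids == "v3"], 0.07)   # complement then keep
  expect_equal(h$beta_out[h$variant_ids == "v5"], -0.03)  # eaf disagreement flips
  expect_equal(h$beta_out[h$variant_ids == "v6"], 0.04)
  expect_equal(h$dropped_palindromes, 1L)
  expect_equal(h$flips, 2L)

  expect_equal(suppressWarnings(
    harmonize(e, o, palindrome_action = "drop"))$dropped_palindromes, 3L)
  expect_error(harmonize(rec("z", "A", "G", 0.1), rec("z", "A", "C", 0.1)),
               "no harmonizable")
})

test_that("harmonization is idempotent", {
  e <- rbind(rec("v1", "A", "G", 0.10, eaf = 0.2),
             rec("v2", "A", "G", 0.20, eaf = 0.2),
             rec("v3", "C", "G", 0.15, eaf = 0.1))
  o <- rbind(rec("v1", "G", "A", 0.05, eaf = 0.8),
             rec("v2", "T", "C", 0.07, eaf = 0.2),
             rec("v3", "G", "C", -0.02, eaf = 0.93))
  h1 <- harmonize(e, o)
  o2 <- e
  o2$beta <- h1$beta_out[match(o2$variant_id, h1$variant_ids)]
  o2$se <- h1$se_out[match(o2$variant_id, h1$variant_ids)]
  h2 <- harmonize(e, o2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$beta_exp, h1$beta_exp)
  expect_equal(h2$flips, 0L)
})

test_that("relabeling both studies' alleles leaves MR estimates unchanged", {
  e <- rbind(rec("v1", "A", "G", 0.10), rec("v2", "T", "C", 0.20),
             rec("v3", "A", "C", 0.15))
  o <- rbind(rec("v1", "A", "G", 0.05), rec("v2", "T", "C", 0.09),
             rec("v3", "A", "C", 0.06))
  base <- ivw(harmonize(e, o))$result
  e2 <- e; o2 <- o
  for (d in c("e2", "o2")) {
    x <- get(d)
    tmp <- x$effect_allele[2]
    x$effect_allele[2] <- x$other_allele[2]
    x$other_allele[2] <- tmp
    x$beta[2] <- -x$beta[2]
    x$eaf[2] <- 1 - x$eaf[2]
    assign(d, x)
  }
  flipped <- ivw(harmonize(e2, o2))$result
  expect_equal(flipped$beta, base$beta, tolerance = 1e-12)
  expect_equal(flipped$se, base$se, tolerance = 1e-12)
})
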