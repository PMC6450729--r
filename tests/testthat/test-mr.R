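test_that("wald ratio closed forms and null-instrument error", {
  expect_equal(wald_ratio(1.0, 0.5, 0.1), list(ratio = 0.5, se = 0.1))
  expect_equal(wald_ratio(0.2, 0.05, 0.02), list(ratio = 0.25, se = 0.1))
  expect_error(wald_ratio(0, 0.05, 0.02), "null instrument")
  ## second-order SE is never smaller than first-order
  so <- wald_ratio(0.2, 0.05, 0.02, se_exp = 0.05, second_order = TRUE)
  expect_gt(so$se, 0.1)
})

test_that("IVW matches the hand-computed example and degenerates to Wald at k=1", {
  h <- make_hset(c(0.1, 0.2, 0.3), c(0.02, 0.05, 0.06), c(0.01, 0.02, 0.015))
  res <- ivw(h)
  expect_equal(res$result$beta, 125 / 600, tolerance = 1e-9)  # 0.208333
  expect_equal(res$het$Q, 5 / 24, tolerance = 1e-9)           # 0.208333
  expect_equal(res$het$I2, 0)

  h1 <- make_hset(0.2, 0.05, 0.02)
  one <- ivw(h1)$result
  wr <- wald_ratio(0.2, 0.05, 0.02)
  expect_equal(one$beta, wr$ratio)
  expect_equal(one$se, wr$se)
  expect_null(ivw(h1)$het)
})

test_that("IVW, Q, I2 match the brute-force oracle on random sets", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:12, 1)
    bx <- rnorm(k, 0.2, 0.05)
    by <- rnorm(k, 0.05, 0.03)
    sy <- runif(k, 0.01, 0.05)
    h <- make_hset(bx, by, sy)
    got <- ivw(h)
    ora <- oracle_ivw(bx, by, sy)
    expect_equal(got$result$beta, ora$beta, tolerance = 1e-12)
    expect_equal(got$het$Q, ora$Q, tolerance = 1e-12)
    expect_equal(got$het$I2, ora$I2, tolerance = 1e-12)
    expect_equal(got$result$se, ora$se_re, tolerance = 1e-12)
    expect_equal(ivw(h, model = "fixed")$result$se, ora$se_fixed,
                 tolerance = 1e-12)
  }
})

test_that("Egger recovers exact lines and enforces k >= 3", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_hset(bx, 0.5 + 1.0 * bx, rep(0.02, 4))
  eg <- mr_egger(h)
  expect_equal(eg$slope$beta, 1.0, tolerance = 1e-9)
  expect_equal(eg$intercept$beta, 0.5, tolerance = 1e-9)

  h0 <- make_hset(bx, 2 * bx, rep(0.02, 4))
  expect_equal(mr_egger(h0)$intercept$beta, 0, tolerance = 1e-9)
  expect_error(mr_egger(make_hset(bx[1:2], bx[1:2], rep(0.02, 2))),
               "insufficient instruments")

  ## orientation: flipping an instrument's signs leaves the fit unchanged
  h2 <- make_hset(c(-0.1, 0.2, 0.3, 0.4) * c(1, 1, 1, 1),
                  c(-(0.5 + 0.1), 0.5 + 0.2, 0.5 + 0.3, 0.5 + 0.4),
                  rep(0.02, 4))
  expect_equal(mr_egger(h2)$slope$beta, 1.0, tolerance = 1e-9)
})

test_that("weighted median interpolation matches the midpoint rule", {
  h <- make_hset(rep(1, 4), c(1, 2, 3, 4), 1 / sqrt(c(0.1, 0.4, 0.4, 0.1)))
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 2.5)
  h2 <- make_hset(rep(1, 3), c(1, 2, 9), rep(1, 3))
  expect_equal(weighted_median(h2, n_boot = 50, seed = 1)$beta, 2)
  expect_error(weighted_median(make_hset(c(1, 1), c(1, 2), c(1, 1))),
               "insufficient")
  set.seed(11)
  for (rep in 1:15) {
    k <- sample(3:12, 1)
    v <- rnorm(k); w <- runif(k, 0.1, 2)
    expect_equal(weighted_median_est(v, w), oracle_weighted_median(v, w),
                 tolerance = 1e-12)
  }
})

test_that("weighted median bootstrap SE is reproducible under its seed", {
  h <- draw_hset(10, 0.2)
  a <- weighted_median(h, n_boot = 200, seed = 9)
  b <- weighted_median(h, n_boot = 200, seed = 9)
  expect_identical(a$se, b$se)
  expect_equal(a$seed, 9)
})

test_that("unit equivariance: scaling exposure betas by c scales estimates by 1/c", {
  set.seed(3)
  h <- draw_hset(12, 0.25)
  cc <- 2.5
  hs <- harmonized_set(h$variant_ids, h$beta_exp * cc, h$se_exp * cc,
                       h$beta_out, h$se_out)
  expect_equal(ivw(hs)$result$beta, ivw(h)$result$beta / cc, tolerance = 1e-9)
  expect_equal(mr_egger(hs)$slope$beta, mr_egger(h)$slope$beta / cc,
               tolerance = 1e-9)
  expect_equal(weighted_median(hs, 100, 5)$beta,
               weighted_median(h, 100, 5)$beta / cc, tolerance = 1e-9)
})

test_that("leave-one-out flags single-SNP drivers and not homogeneous sets", {
  h <- make_hset(rep(0.2, 3), rep(0.05, 3), rep(0.02, 3))
  loo <- leave_one_out(h)
  expect_equal(nrow(loo$table), 4L)
  expect_equal(length(unique(round(loo$table$beta, 12))), 1L)
  expect_true(loo$no_single_driver)

  ## one outlier that doubles the pooled estimate
  h2 <- make_hset(c(rep(0.2, 4), 0.2), c(rep(0.02, 4), 0.30),
                  c(rep(0.02, 4), 0.01))
  loo2 <- leave_one_out(h2)
  expect_false(loo2$no_single_driver)
  full <- loo2$table$beta[loo2$table$left_out == "all"]
  drop5 <- loo2$table$beta[loo2$table$left_out == "v5"]
  expect_lt(drop5, full / 2)
})

test_that("Steiger direction reflects relative variance explained", {
  h <- make_hset(rep(0.2, 5), rep(0.001, 5), rep(0.02, 5), rep(0.01, 5))
  s <- steiger(h, n_exp = 1e5, n_out = 1e5)
  expect_true(s$direction_ok)
  expect_lt(s$pval, 1e-10)

  heq <- make_hset(0.2, 0.2, 0.01, 0.01)
  seq_ <- steiger(heq, 5e4, 5e4)
  expect_false(seq_$direction_ok)       # equal r2: not supported
  expect_equal(seq_$z, 0)
  expect_equal(seq_$pval, 1)

  ## reversed causal model: outcome is upstream, instruments explain more there
  set.seed(21)
  rev <- simulate_two_sample(sim_config(seed = 77, theta = 0.4))
  ids <- rev$truth$instrument_ids
  e <- rev$exposure$data; o <- rev$outcome$data
  hrev <- harmonize(o[o$variant_id %in% ids, ], e[e$variant_id %in% ids, ],
                    n_exp = 1e5, n_out = 1e5)
  expect_false(steiger(hrev)$direction_ok)
  expect_error(steiger(heq, -1, 10), "positive")
})

test_that("F-statistic closed forms", {
  expect_equal(as.numeric(f_statistic(make_hset(0.1, 0, 1, 0.02))), 25)
  h0 <- make_hset(c(1e-12, 1e-12), c(0, 0), c(1, 1), c(1, 1))
  expect_equal(as.numeric(f_statistic(h0)), 0, tolerance = 1e-20)
  expect_true(attr(f_statistic(make_hset(0.1, 0, 1, 0.02)), "strong"))
})

test_that("Q under the no-heterogeneity null has mean ~ k-1", {
  set.seed(19)
  k <- 10
  n_rep <- 400
  qs <- replicate(n_rep, {
    bx <- rnorm(k, 0.25, 0.02)
    h <- make_hset(rnorm(k, bx, 1e-6), rnorm(k, 0.2 * bx, 0.02),
                   rep(0.02, k), rep(1e-6, k))
    ivw(h)$het$Q
  })
  se_mean <- sd(qs) / sqrt(n_rep)
  expect_lt(abs(mean(qs) - (k - 1)), 3 * se_mean)
})

test_that("reverse MR stays null under a forward-only model and battery assembles", {
  sim <- simulate_two_sample(sim_config(seed = 5, theta = 0.3))
  rev <- reverse_mr(sim$outcome, sim$exposure, sim$ld, seed = 2, n_boot = 100)
  if (!isFALSE(rev$eligible)) {
    expect_s3_class(rev, "mr_battery")
  }
  ids <- sim$truth$instrument_ids
  e <- sim$exposure$data; o <- sim$outcome$data
  h <- harmonize(e[e$variant_id %in% ids, ], o[o$variant_id %in% ids, ],
                 n_exp = 1e5, n_out = 1e5)
  bat <- mr_battery(h, n_boot = 100, seed = 4)
  tab <- as.data.frame(bat)
  expect_setequal(tab$method, c("ivw", "egger_slope", "egger_intercept",
                                "weighted_median"))
  expect_true(all(is.finite(tab$beta)))
  expect_true(bat$steiger$direction_ok)
})
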