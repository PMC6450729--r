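test_that("Wakefield log-ABF limits and arithmetic", {
  ## null z shrinks: 0.5 log(1 - r) < 0
  expect_lt(wakefield_abf(0, 0.1, prior_sd = 0.2), 0)
  ## uninformative limit: V -> Inf gives log-ABF -> 0
  expect_equal(wakefield_abf(0.5, 1e6, prior_sd = 0.2), 0, tolerance = 1e-9)
  ## direct evaluation of the formula at beta 0.1, se 0.02, W 0.04
  z <- 0.1 / 0.02; r <- 0.04 / (0.02^2 + 0.04)
  expect_equal(wakefield_abf(0.1, 0.02, prior_sd = 0.2),
               0.5 * log(1 - r) + 0.5 * z^2 * r, tolerance = 1e-12)
  expect_error(wakefield_abf(0.1, 0), "positive")
})

test_that("shared strong signals colocalize; null panels land on H0", {
  k <- 20
  beta <- c(rep(0.001, 10), 0.25, rep(0.001, 9))
  panel <- region_panel("shared", paste0("v", 1:k), beta, rep(0.01, k),
                        beta, rep(0.01, k))
  res <- coloc_region(panel)
  expect_gt(res$pph[["H4"]], 0.95)
  expect_true(res$colocalized)
  expect_equal(res$top_variant, "v11")

  null_panel <- region_panel("null", paste0("v", 1:5), rep(0.001, 5),
                             rep(0.02, 5), rep(-0.002, 5), rep(0.02, 5))
  expect_gt(coloc_region(null_panel)$pph[["H0"]], 0.9)
})

test_that("posterior probabilities match the enumeration oracle to 1e-9", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(3:12, 1)
    b1 <- rnorm(k, 0, 0.05); b2 <- rnorm(k, 0, 0.05)
    if (rep %% 2) { i <- sample(k, 1); b1[i] <- 0.2; b2[i] <- 0.15 }
    s1 <- runif(k, 0.02, 0.05); s2 <- runif(k, 0.02, 0.05)
    panel <- region_panel("p", paste0("v", 1:k), b1, s1, b2, s2,
                          type1 = "quantitative", type2 = "binary")
    got <- coloc_region(panel)
    ora <- oracle_coloc(b1, s1, b2, s2, sd1 = 0.15, sd2 = 0.20)
    expect_equal(unname(got$pph), unname(ora), tolerance = 1e-9)
  }
})

test_that("pph and per-variant posteriors normalize exactly", {
  set.seed(8)
  k <- 30
  panel <- region_panel("n", paste0("v", 1:k), rnorm(k, 0, 0.3),
                        runif(k, 0.005, 0.02), rnorm(k, 0, 0.3),
                        runif(k, 0.005, 0.02))
  res <- coloc_region(panel)   # z up to ~40: log-space survives
  expect_equal(sum(res$pph), 1, tolerance = 1e-9)
  expect_equal(sum(res$h4_posterior), 1, tolerance = 1e-9)
  expect_true(all(res$pph >= 0))
})

test_that("relabeling traits swaps H1 and H2 and fixes H0, H3, H4", {
  set.seed(12)
  k <- 8
  b1 <- c(0.2, rnorm(k - 1, 0, 0.01)); s1 <- rep(0.02, k)
  b2 <- rnorm(k, 0, 0.01); s2 <- rep(0.03, k)
  panel <- region_panel("a", paste0("v", 1:k), b1, s1, b2, s2,
                        type1 = "binary", type2 = "binary")
  swapped <- region_panel("a", paste0("v", 1:k), b2, s2, b1, s1,
                          type1 = "binary", type2 = "binary")
  ra <- coloc_region(panel); rb <- coloc_region(swapped)
  expect_equal(ra$pph[["H1"]], rb$pph[["H2"]], tolerance = 1e-12)
  expect_equal(ra$pph[["H2"]], rb$pph[["H1"]], tolerance = 1e-12)
  for (hyp in c("H0", "H3", "H4")) {
    expect_equal(ra$pph[[hyp]], rb$pph[[hyp]], tolerance = 1e-12)
  }
})

test_that("a single-variant panel reports H3 = 0 with a warning", {
  panel <- region_panel("one", "v1", 0.2, 0.02, 0.2, 0.02)
  expect_warning(res <- coloc_region(panel), "single-variant")
  expect_equal(res$pph[["H3"]], 0)
  expect_equal(sum(res$pph), 1, tolerance = 1e-12)
})

test_that("simulated architectures produce the matching dominant hypothesis", {
  shared <- simulate_coloc_region(sim_config(seed = 61, m_variants = 100,
                                             coloc_mode = "shared"))
  rs <- coloc_region(shared$panel)
  expect_gt(rs$pph[["H4"]], 0.9)

  distinct <- simulate_coloc_region(sim_config(seed = 62, m_variants = 100,
                                               ld_rho = 0.2,
                                               coloc_mode = "distinct"))
  rd <- coloc_region(distinct$panel)
  expect_gt(rd$pph[["H3"]], 0.5)

  none <- simulate_coloc_region(sim_config(seed = 63, m_variants = 100,
                                           coloc_mode = "none"))
  expect_gt(coloc_region(none$panel)$pph[["H0"]], 0.9)

  t1 <- simulate_coloc_region(sim_config(seed = 64, m_variants = 100,
                                         coloc_mode = "trait1"))
  expect_gt(coloc_region(t1$panel)$pph[["H1"]], 0.5)
})

test_that("coloc_table lays out one row per region", {
  p <- region_panel("r1", paste0("v", 1:3), c(0.2, 0, 0), rep(0.02, 3),
                    c(0.2, 0, 0), rep(0.02, 3))
  tab <- coloc_table(list(coloc_region(p)))
  expect_equal(names(tab)[1:7],
               c("region_id", "n_variants", "PPH0", "PPH1", "PPH2", "PPH3", "PPH4"))
  expect_equal(tab$region_id, "r1")
})
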