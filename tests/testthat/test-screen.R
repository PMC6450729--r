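test_that("BH adjustment matches hand computation and edge cases", {
  expect_false(any(fdr_bh(rep(1, 6))$significant))
  got <- fdr_bh(c(0.001, 0.01, 0.04, 0.5))
  expect_equal(got$adjusted, c(0.004, 0.02, 0.04 * 4 / 3, 0.5),
               tolerance = 1e-12)
  expect_equal(got$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdr_bh(0.04)$adjusted, 0.04)
  expect_length(fdr_bh(numeric())$adjusted, 0)
})

test_that("BH equals the reference implementation on short vectors", {
  set.seed(14)
  for (m in 1:8) {
    for (rep in 1:25) {
      p <- runif(m)
      expect_equal(fdr_bh(p)$adjusted, p.adjust(p, method = "BH"),
                   tolerance = 1e-12)
    }
  }
})

test_that("empty library gives an empty report", {
  out <- sumstats(data.frame(variant_id = "rs1", effect_allele = "A",
                             other_allele = "G", beta = 0.1, se = 0.02,
                             pval = 0.5), "als", "binary")
  rep <- run_mr_screen(trait_library(list(), out), NULL)
  expect_equal(nrow(rep$table), 0L)
  expect_length(rep$final_causal_set, 0L)
})

test_that("the screen recovers planted causal traits and logs null ones", {
  built <- build_library(seed = 400)
  rep <- suppressWarnings(run_mr_screen(built$lib, built$ld,
                                        screen_config(n_boot = 300)))
  expect_equal(nrow(rep$table), 8L)
  expect_setequal(rep$final_causal_set,
                  c("causal_trait1_published", "causal_trait1_ukbb"))
  expect_true(all(rep$table$pass_phase1[grepl("causal", rep$table$trait_id)]))
  ## invariant chain: replicated => pass_sensitivity => pass_phase1
  expect_true(all(!rep$table$replicated | rep$table$pass_sensitivity))
  expect_true(all(!rep$table$pass_sensitivity | rep$table$pass_phase1))
})

test_that("gate booleans are recomputable from the report's own numbers", {
  built <- build_library(seed = 401)
  cfg <- screen_config(n_boot = 200)
  rep <- suppressWarnings(run_mr_screen(built$lib, built$ld, cfg))
  t <- rep$table
  expect_equal(t$pass_phase1,
               !is.na(t$ivw_pval) & t$ivw_pval <= cfg$phase1_alpha)
  expect_equal(t$pass_sensitivity,
               t$pass_phase1 &
                 !is.na(t$egger_pval) & t$egger_pval <= cfg$sensitivity_alpha &
                 !is.na(t$wm_pval) & t$wm_pval <= cfg$sensitivity_alpha)
  recomputed <- vapply(seq_len(nrow(t)), function(i) {
    if (!t$pass_sensitivity[i]) return(FALSE)
    other <- which(t$category == t$category[i] &
                     t$cohort_tag != t$cohort_tag[i])
    if (!length(other)) return(TRUE)
    any(t$pass_sensitivity[other] &
          sign(t$ivw_beta[other]) == sign(t$ivw_beta[i]))
  }, logical(1))
  expect_equal(t$replicated, recomputed)
})

test_that("tightening thresholds never enlarges the final causal set", {
  built <- build_library(seed = 402)
  loose <- suppressWarnings(run_mr_screen(built$lib, built$ld,
                                          screen_config(n_boot = 200)))
  tight <- suppressWarnings(run_mr_screen(built$lib, built$ld,
    screen_config(n_boot = 200, phase1_alpha = 0.001,
                  sensitivity_alpha = 0.001, p_thresh = 1e-10)))
  expect_true(all(tight$final_causal_set %in% loose$final_causal_set))
})

test_that("the LDSC screen controls FDR over a synthetic trait library", {
  cor_traits <- list()
  outcome_sim <- simulate_ldsc(sim_config(seed = 900, m_variants = 3000,
                                          M = 3000, rg = 0.5))
  for (i in 1:8) {
    s <- simulate_ldsc(sim_config(seed = 900 + i, m_variants = 3000, M = 3000,
                                  rg = if (i <= 2) 0.5 else 0))
    ## share the outcome z by reusing z1 of the outcome sim for trait pairs:
    cor_traits[[sprintf("trait%02d", i)]] <- list(z = s$z1, n = s$n1,
                                                  z2 = s$z2)
  }
  ## outcome: for correlated traits use the paired draw, else independent
  res <- run_ldsc_screen(
    traits = lapply(cor_traits, function(t) list(z = t$z, n = t$n)),
    outcome = list(z = outcome_sim$z1, n = outcome_sim$n1),
    lds = outcome_sim$lds, n_blocks = 50)
  expect_equal(nrow(res$table), 8L)
  expect_equal(res$family_size, sum(res$table$status == "ok"))
  ## independent traits: none should be flagged often; just check structure
  expect_true(all(c("rg", "fdr_pval", "significant") %in% names(res$table)))

  ## paired construction: trait z2 is genuinely correlated with its z1 and
  ## must be scored against its own LD scores and sample sizes
  ps <- simulate_ldsc(sim_config(seed = 901, m_variants = 3000, M = 3000,
                                 rg = 0.5))
  paired <- run_ldsc_screen(
    traits = list(corr = list(z = ps$z2, n = ps$n2)),
    outcome = list(z = ps$z1, n = ps$n1),
    lds = ps$lds, n_blocks = 50)
  expect_true(paired$table$significant[1])
  expect_lt(abs(paired$table$rg - 0.5), 3 * paired$table$rg_se)
})
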