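test_that("the same seed reproduces cohorts and GWAS triplets bit-for-bit", {
  cfg <- sim_config(n_snps = 10, n_snps_mediator = 10, n_per_gwas = 500,
                    seed = 71)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  t1 <- suppressMessages(make_three_gwas(cfg))
  t2 <- suppressMessages(make_three_gwas(cfg))
  expect_identical(t1$exposure, t2$exposure)
  expect_identical(t1$truth, t2$truth)
})

test_that("truth records and variance budgets behave as configured", {
  cfg <- sim_config(n_snps = 20, n_snps_mediator = 5, n_per_gwas = 500,
                    effect_x_to_m = 0.25, effect_m_to_y = 0.4,
                    direct_x_to_y = 0.1, seed = 72)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth
  expect_equal(tr$mediated_effect, 0.25 * 0.4)
  expect_equal(sum(tr$gamma != 0), 20)
  expect_equal(sum(tr$alpha != 0), 5)
  expect_true(all(tr$gamma[!tr$is_exposure_snp] == 0))
  expect_true(all(sim$cohort$genotypes %in% 0:2))
  # unit-variance targets for the quantitative traits
  expect_lt(abs(var(sim$cohort$exposure) - 1), 0.25)
  expect_lt(abs(var(sim$cohort$mediator) - 1), 0.25)
  # an infeasible variance budget is refused
  expect_error(simulate_cohort(sim_config(n_snps = 50, gamma_sd = 0.5,
                                          n_per_gwas = 100, seed = 1)),
               "variance budget")
})

test_that("the zero-noise limit gives M = a X exactly", {
  cfg <- sim_config(n_snps = 10, n_snps_mediator = 0, n_per_gwas = 300,
                    effect_x_to_m = 1, seed = 73)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$cohort$mediator, sim$cohort$exposure)
})

test_that("a null model yields Wald ratios centred on zero", {
  cfg <- sim_config(n_snps = 40, n_snps_mediator = 0, n_per_gwas = 2000,
                    effect_x_to_m = 0, effect_m_to_y = 0, direct_x_to_y = 0,
                    seed = 74)
  trip <- suppressMessages(make_three_gwas(cfg))
  h <- harmonize(trip$exposure, trip$outcome)
  wr <- wald_ratios(h)
  z <- wr$ratio / wr$ratio_se
  expect_lt(abs(mean(z)), 3 / sqrt(nrow(wr)))
})

test_that("linear GWAS scans equal the univariate OLS oracle", {
  cfg <- sim_config(n_snps = 5, n_snps_mediator = 0, n_per_gwas = 400,
                    seed = 75)
  sim <- simulate_cohort(cfg)
  ids <- 1:400
  tab <- suppressMessages(gwas_scan(sim$cohort, "exposure", ids))
  for (j in 1:5) {
    fit <- lm(sim$cohort$exposure[ids] ~ sim$cohort$genotypes[ids, j])
    expect_equal(tab$beta[j], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(tab$se[j], unname(summary(fit)$coefficients[2, 2]),
                 tolerance = 1e-10)
  }
  expect_equal(tab$eaf, unname(colMeans(sim$cohort$genotypes[ids, 1:5]) / 2))
})

test_that("a permuted trait gives uniform scan p-values", {
  set.seed(76)
  cfg <- sim_config(n_snps = 60, n_snps_mediator = 0, n_per_gwas = 800,
                    seed = 76)
  sim <- simulate_cohort(cfg)
  sim$cohort$exposure <- sample(sim$cohort$exposure)
  tab <- suppressMessages(gwas_scan(sim$cohort, "exposure", 1:800))
  expect_gt(ks.test(tab$pval, "punif")$p.value, 0.01)
})

test_that("sample overlap controls the shared exposure/outcome individuals", {
  cfg0 <- sim_config(n_snps = 5, n_per_gwas = 200, overlap_prop = 0, seed = 77)
  t0 <- suppressMessages(make_three_gwas(cfg0))
  expect_length(intersect(t0$subsamples$exposure, t0$subsamples$outcome), 0)
  expect_length(intersect(t0$subsamples$exposure, t0$subsamples$mediator), 0)

  cfg1 <- sim_config(n_snps = 5, n_per_gwas = 200, overlap_prop = 1, seed = 77)
  t1 <- suppressMessages(make_three_gwas(cfg1))
  expect_identical(t1$subsamples$exposure, t1$subsamples$outcome)

  cfg5 <- sim_config(n_snps = 5, n_per_gwas = 200, overlap_prop = 0.5, seed = 77)
  t5 <- suppressMessages(make_three_gwas(cfg5))
  expect_length(intersect(t5$subsamples$exposure, t5$subsamples$outcome), 100)
})

test_that("the summary-level route matches the configured sampling distribution", {
  cfg <- sim_config(n_snps = 200, n_snps_mediator = 200, n_per_gwas = 50000,
                    effect_x_to_m = 0.3, effect_m_to_y = 0.4, seed = 78)
  trip <- simulate_summary_gwas(cfg)
  tr <- trip$truth
  # standardized deviations from the true marginal effects are ~ N(0, 1)
  ix <- match(trip$exposure$variant_id, tr$variant_id)
  im <- match(trip$mediator$variant_id, tr$variant_id)
  z_x <- (trip$exposure$beta - tr$gamma[ix]) / trip$exposure$se
  z_m <- (trip$mediator$beta - (0.3 * tr$gamma[im] + tr$alpha[im])) /
    trip$mediator$se
  expect_lt(abs(mean(z_x)), 0.25)
  expect_lt(abs(sd(z_x) - 1), 0.15)
  expect_gt(ks.test(z_m, "pnorm")$p.value, 0.01)
  # the route refuses conditions it cannot represent
  expect_error(simulate_summary_gwas(
    sim_config(n_snps = 5, overlap_prop = 0.5, seed = 1)), "overlap")
})

test_that("directional pleiotropy is detectable through the Egger intercept", {
  hits <- 0L
  for (i in 1:30) {
    cfg <- sim_config(n_snps = 50, n_snps_mediator = 0, n_per_gwas = 50000,
                      effect_x_to_m = 0.3, pleiotropy_frac = 1,
                      pleiotropy_sd = 0.005, pleiotropy_mean = 0.03,
                      seed = 7900 + i)
    trip <- simulate_summary_gwas(cfg)
    h <- harmonize(trip$exposure, trip$outcome)
    h <- h[h$pval_x < 5e-8, , drop = FALSE]
    if (nrow(h) < 10) next
    if (egger_intercept_test(h)$significant) hits <- hits + 1L
  }
  expect_gte(hits, 24)
})
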