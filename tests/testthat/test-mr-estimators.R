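test_that("Wald ratios follow the delta-method closed form", {
  h <- make_h(beta_x = 0.2, beta_y = 0.1, se_y = 0.02)
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$ratio_se, 0.1)

  # negative beta_x flips the ratio sign, not the SE
  h2 <- make_h(beta_x = -0.2, beta_y = 0.1, se_y = 0.02)
  wr2 <- wald_ratios(h2)
  expect_equal(wr2$ratio, -0.5)
  expect_equal(wr2$ratio_se, 0.1)

  set.seed(21)
  h3 <- random_h(10)
  wr3 <- wald_ratios(h3)
  expect_equal(wr3$ratio, h3$beta_y / h3$beta_x)
  expect_equal(wr3$ratio_se, h3$se_y / abs(h3$beta_x))

  h4 <- make_h(beta_x = c(0, 0.2), beta_y = c(0.1, 0.1))
  expect_warning(wr4 <- wald_ratios(h4), "beta_x = 0")
  expect_equal(nrow(wr4), 1)
})

test_that("IVW equals the closed-form inverse-variance weighted mean", {
  # degenerate: all ratios equal -> B is the common ratio, Q = 0
  h <- make_h(beta_x = c(0.1, 0.2, 0.4), beta_y = c(0.05, 0.10, 0.20),
              se_y = c(0.02, 0.03, 0.05))
  est <- mr_ivw(h, model = "fixed")
  expect_equal(est$b, 0.5)
  expect_equal(attr(est, "Q"), 0)

  expect_error(mr_ivw(make_h(0.1, 0.05)[1, ]), "at least 2")

  # 3-pair example against an independently computed weighted mean
  r <- c(0.5, 0.3, 0.8); s <- c(0.1, 0.2, 0.4)
  h3 <- make_h(beta_x = rep(1, 3), beta_y = r, se_y = s)
  w <- 1 / s^2
  expect_equal(mr_ivw(h3, model = "fixed")$b, sum(w * r) / sum(w))
  expect_equal(mr_ivw(h3, model = "fixed")$se, sqrt(1 / sum(w)))

  # random tables, machine precision
  for (seed in 1:5) {
    h <- random_h(10, seed = seed, het = 0.05)
    wr <- wald_ratios(h)
    w <- 1 / wr$ratio_se^2
    expect_equal(mr_ivw(h, model = "fixed")$b, sum(w * wr$ratio) / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("random-effects IVW inflates the SE only under excess heterogeneity", {
  h_hom <- make_h(beta_x = rep(0.2, 5), beta_y = rep(0.1, 5), se_y = 0.02)
  f <- mr_ivw(h_hom, model = "fixed")
  r <- mr_ivw(h_hom, model = "random")
  expect_equal(r$se, f$se)  # Q = 0: max(1, .) clamps at 1

  h_het <- random_h(20, het = 0.5, seed = 3)
  f <- mr_ivw(h_het, model = "fixed")
  r <- mr_ivw(h_het, model = "random")
  Q <- attr(f, "Q")
  expect_equal(r$se, f$se * max(1, sqrt(Q / 19)))
  # auto picks random effects exactly when the Q test rejects
  a <- mr_ivw(h_het, model = "auto")
  expect_equal(a$model, if (attr(f, "Q_pval") < 0.05) "random" else "fixed")
})

test_that("Egger recovers a line through the origin and a constant offset", {
  bx <- c(0.1, 0.15, 0.2, 0.3, 0.4)
  h <- make_h(bx, 0.6 * bx, se_y = 0.02)
  eg <- mr_egger(h)
  expect_equal(eg$slope$b, 0.6, tolerance = 1e-10)
  expect_equal(eg$intercept$estimate, 0, tolerance = 1e-10)

  # constant additive pleiotropy appears in the intercept (equal weights)
  set.seed(22)
  h2 <- make_h(bx, 0.6 * bx + 0.03 + rnorm(5, 0, 1e-4), se_y = 0.02)
  eg2 <- mr_egger(h2)
  expect_equal(eg2$intercept$estimate, 0.03, tolerance = 0.02)

  expect_error(mr_egger(make_h(c(0.1, 0.2), c(0.1, 0.1))), "at least 3")
})

test_that("Egger matches an independent weighted-regression oracle", {
  for (seed in 1:5) {
    h <- random_h(5, seed = seed, het = 0.1)
    # orientation: flip pairs so beta_x >= 0, then weighted lm as the oracle
    sgn <- ifelse(h$beta_x < 0, -1, 1)
    d <- data.frame(x = sgn * h$beta_x, y = sgn * h$beta_y)
    fit <- lm(y ~ x, data = d, weights = 1 / h$se_y^2)
    eg <- mr_egger(h)
    expect_equal(eg$slope$b, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(eg$intercept$estimate, unname(coef(fit)[1]), tolerance = 1e-10)
    # SE convention: lm's sigma-scaled SE, but never deflated below sigma = 1
    sm <- summary(fit)
    expected_se <- unname(sm$coefficients[2, 2]) * max(1, sm$sigma) / sm$sigma
    expect_equal(eg$slope$se, expected_se, tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the cumulative weights at one half", {
  h <- make_h(beta_x = rep(1, 3), beta_y = c(0.1, 0.5, 0.9), se_y = 0.1)
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$b, 0.5)

  # overwhelming weight pulls the estimate to that ratio
  h2 <- make_h(beta_x = rep(1, 4), beta_y = c(0.1, 0.4, 0.9, 0.4),
               se_y = c(1, 1e-4, 1, 1))
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$b, 0.4,
               tolerance = 1e-3)

  # 7 weighted ratios against the brute-force crossing oracle
  for (seed in 1:5) {
    h3 <- random_h(7, seed = seed, het = 0.2)
    wr <- wald_ratios(h3)
    expect_equal(mr_weighted_median(h3, n_boot = 50, seed = 1)$b,
                 oracle_weighted_median(wr$ratio, 1 / wr$ratio_se^2),
                 tolerance = 1e-10)
  }
})

test_that("mode estimators find the densest ratio cluster", {
  h <- make_h(beta_x = rep(0.2, 4), beta_y = rep(0.08, 4), se_y = 0.02)
  expect_equal(mr_mode(h, weighted = TRUE, n_boot = 50, seed = 1)$b, 0.4)

  # bimodal ratios: heavier cluster near 0.4, lighter near 1.2
  set.seed(23)
  ratios <- c(rnorm(12, 0.4, 0.02), rnorm(5, 1.2, 0.02))
  h2 <- make_h(beta_x = rep(1, 17), beta_y = ratios, se_y = 0.05)
  est <- mr_mode(h2, weighted = FALSE, n_boot = 50, seed = 1)
  expect_lt(abs(est$b - 0.4), 0.1)

  # equal weights: simple and weighted modes coincide
  h3 <- make_h(beta_x = rep(1, 6), beta_y = c(0.1, 0.35, 0.4, 0.45, 0.8, 0.9),
               se_y = 0.05)
  expect_equal(mr_mode(h3, weighted = TRUE, n_boot = 20, seed = 2)$b,
               mr_mode(h3, weighted = FALSE, n_boot = 20, seed = 2)$b)
})

test_that("estimators converge to the dominant pair's Wald ratio", {
  h <- make_h(beta_x = c(0.2, 0.1, 0.3, 0.15),
              beta_y = c(0.12, 0.01, 0.33, 0.02),
              se_y = c(1e-5, 0.5, 0.5, 0.5))
  target <- 0.12 / 0.2
  expect_equal(mr_ivw(h, model = "fixed")$b, target, tolerance = 1e-6)
  expect_equal(mr_weighted_median(h, n_boot = 20, seed = 1)$b, target,
               tolerance = 1e-6)
  expect_equal(mr_mode(h, weighted = TRUE, n_boot = 20, seed = 1)$b, target,
               tolerance = 0.02)
})

test_that("estimates are scale-equivariant in the exposure and OR round-trips", {
  h <- random_h(10, het = 0.1, seed = 31)
  c_scale <- 2.5
  h2 <- make_h(beta_x = h$beta_x * c_scale, beta_y = h$beta_y,
               se_x = h$se_x * c_scale, se_y = h$se_y)
  f1 <- mr_fit(h, n_boot = 50, seed = 9)
  f2 <- mr_fit(h2, n_boot = 50, seed = 9)
  expect_equal(coef(f2)[c("ivw", "egger", "weighted_median")],
               coef(f1)[c("ivw", "egger", "weighted_median")] / c_scale,
               tolerance = 1e-6)

  est <- f1$estimates
  expect_equal(log(est$or), est$b)
  expect_equal(log(est$ci_high) - log(est$ci_low), 2 * 1.96 * est$se)
  expect_true(all(est$ci_low < est$or & est$or < est$ci_high))
})

test_that("causal calls implement the direction-consistency and IVW rules", {
  panel <- function(bs, p_ivw) {
    est <- data.frame(method = c("ivw", "egger", "weighted_median",
                                 "simple_mode", "weighted_mode"),
                      b = bs, pval = c(p_ivw, rep(0.5, 4)))
    causal_call(est)
  }
  # the telomere-length -> lung-cancer configuration: five positive effects,
  # IVW OR = 1.411 at p < 1e-4 -> significant risk call
  cc <- panel(c(log(1.411), 0.30, 0.36, 0.33, 0.35), 1e-5)
  expect_true(cc$significant)
  expect_equal(cc$direction, "risk")
  # one discordant sign vetoes significance regardless of p
  cc <- panel(c(0.3, 0.2, 0.25, -0.01, 0.22), 0.001)
  expect_false(cc$significant)
  expect_equal(cc$direction, "null")
  # all negative but IVW p above alpha -> null
  cc <- panel(rep(-0.2, 5), 0.2)
  expect_equal(cc$direction, "null")
  # all negative and significant -> protective
  cc <- panel(rep(-0.2, 5), 0.01)
  expect_equal(cc$direction, "protective")
})

test_that("IVW attains the nominal 5% level on null data", {
  # 50 instruments, no effect, no pleiotropy, 1000 replicates
  n_rep <- 1000
  rej <- vapply(seq_len(n_rep), function(i) {
    set.seed(40000 + i)
    bx_true <- rnorm(50, 0, 0.09)
    se_x <- rep(0.005, 50)
    se_y <- rep(0.02, 50)
    h <- make_h(beta_x = rnorm(50, bx_true, se_x),
                beta_y = rnorm(50, 0, se_y), se_x = se_x, se_y = se_y)
    mr_ivw(h, model = "auto")$pval < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})
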