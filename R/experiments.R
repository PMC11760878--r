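#' @title Calibration, recovery and overlap experiments
#' @description
#' Replicated simulation studies of the pipeline's operating
#' characteristics: type-I error of the IVW and Sobel tests under a
#' mediated null, MR-PRESSO global-test calibration, coverage of the Sobel
#' confidence interval for a known mediated effect, and the effect of
#' exposure/outcome sample overlap on type-I error under a confounded
#' null.  Every experiment derives all randomness from one seed.
#' @name experiments
NULL

select_instruments_h <- function(exposure, outcome, p_threshold = 5e-8) {
  h <- harmonize(exposure, outcome)
  h[h$pval_x < p_threshold, , drop = FALSE]
}

#' Null calibration of the IVW and Sobel tests
#'
#' Replicates a mediated-null study: the exposure has no effect on the
#' mediator (`a = 0`) while the mediator affects the outcome (`b`), so both
#' the exposure-mediator IVW test and the Sobel test of the mediated path
#' are null.  Summary statistics are drawn by the fast asymptotic route;
#' instruments are selected at genome-wide significance.
#'
#' @param n_rep Replicates (default 1000).
#' @param n_snps Instrument SNPs per trait (default 50).
#' @param n_per_gwas GWAS sample size (default 100000).
#' @param b Mediator-outcome log-odds effect (default 0.4).
#' @param model IVW model for the exposure-mediator test (default
#'   `"fixed"`: the null data are homogeneous, and the auto rule is
#'   deliberately conservative because its random-effects branch triggers
#'   on the 5% of null replicates with large Q).
#' @param alpha Test level (default 0.05).
#' @param seed Experiment seed.
#' @return List with `ivw_rejection` and `sobel_rejection` rates and the
#'   replicate count actually evaluated.
#' @export
experiment_null_calibration <- function(n_rep = 1000, n_snps = 50,
                                        n_per_gwas = 1e5, b = 0.4,
                                        model = "fixed",
                                        alpha = 0.05, seed = 1) {
  ivw_rej <- sobel_rej <- logical(0)
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_snps = n_snps, n_snps_mediator = n_snps,
                      n_per_gwas = n_per_gwas, effect_x_to_m = 0,
                      effect_m_to_y = b, seed = child_seed(seed, i))
    trip <- suppressMessages(simulate_summary_gwas(cfg))
    h_xm <- select_instruments_h(trip$exposure, trip$mediator)
    h_my <- select_instruments_h(trip$mediator, trip$outcome)
    if (nrow(h_xm) < 3 || nrow(h_my) < 3) next
    ivw_rej <- c(ivw_rej, mr_ivw(h_xm, model = model)$pval < alpha)
    s1 <- summary_stage_one(h_xm)
    s2 <- mr_ivw(h_my, model = "auto")
    sobel_rej <- c(sobel_rej, sobel_mediation(s1, b2 = s2)$pval < alpha)
  }
  list(ivw_rejection = mean(ivw_rej), sobel_rejection = mean(sobel_rej),
       n_rep = length(ivw_rej))
}

#' MR-PRESSO global-test calibration on clean data
#'
#' Rejection rate of the MR-PRESSO global test at level `alpha` on
#' pleiotropy-free exposure-mediator data.
#'
#' @param n_rep Replicates (default 200).
#' @param n_snps Instrument SNPs (default 50).
#' @param n_per_gwas GWAS sample size (default 20000).
#' @param n_sim MR-PRESSO simulations per replicate (default 1000).
#' @param alpha Test level (default 0.05).
#' @param seed Experiment seed.
#' @return List with `rejection` rate and `n_rep`.
#' @export
experiment_presso_calibration <- function(n_rep = 200, n_snps = 50,
                                          n_per_gwas = 2e4, n_sim = 1000,
                                          alpha = 0.05, seed = 1) {
  rej <- logical(0)
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_snps = n_snps, n_snps_mediator = 0,
                      n_per_gwas = n_per_gwas, effect_x_to_m = 0.3,
                      seed = child_seed(seed, 5000 + i))
    trip <- suppressMessages(simulate_summary_gwas(cfg))
    h <- select_instruments_h(trip$exposure, trip$mediator)
    if (nrow(h) < 4) next
    p <- mr_presso(h, n_sim = n_sim, seed = child_seed(seed, 6000 + i))
    rej <- c(rej, p$global_pval < alpha)
  }
  list(rejection = mean(rej), n_rep = length(rej))
}

#' Coverage of the Sobel interval for a known mediated effect
#'
#' Full individual-level replicates of the two-step analysis: cohorts are
#' simulated with a known mediated effect `a*b`, the three GWAS are
#' scanned, instruments selected, stage 1 estimated by two-stage least
#' squares on the mediator cohort (the analysis' stage-1 method, immune to
#' the regression dilution a summary-level stage 1 inherits from noisy
#' instrument effects), stage 2 by IVW, and the Sobel 95% interval checked
#' against the truth.
#'
#' @param n_rep Replicates (default 100).
#' @param a,b Path coefficients (defaults 0.3 and 0.4; mediated effect
#'   `a*b = 0.12`).
#' @param n_snps Instrument SNPs per trait (default 50).
#' @param n_per_gwas Individuals per trait GWAS (default 20000).
#' @param seed Experiment seed.
#' @return List with `coverage` (proportion of intervals covering `a*b`),
#'   `mean_bm`, and `n_rep`.
#' @export
experiment_mediation_recovery <- function(n_rep = 100, a = 0.3, b = 0.4,
                                          n_snps = 50, n_per_gwas = 2e4,
                                          seed = 1) {
  covered <- logical(0)
  bms <- numeric(0)
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_snps = n_snps, n_snps_mediator = n_snps,
                      n_per_gwas = n_per_gwas, effect_x_to_m = a,
                      effect_m_to_y = b, seed = child_seed(seed, 7000 + i))
    trip <- suppressMessages(make_three_gwas(cfg))
    h_xm <- select_instruments_h(trip$exposure, trip$mediator)
    h_my <- select_instruments_h(trip$mediator, trip$outcome)
    if (nrow(h_xm) < 3 || nrow(h_my) < 3) next
    ids_m <- trip$subsamples$mediator
    s1 <- two_stage_least_squares(
      list(genotypes = trip$cohort$genotypes[ids_m, , drop = FALSE],
           exposure = trip$cohort$exposure[ids_m],
           mediator = trip$cohort$mediator[ids_m]),
      instrument_ids = h_xm$variant_id)
    s2 <- mr_ivw(h_my, model = "auto")
    med <- sobel_mediation(s1, b2 = s2)
    covered <- c(covered, med$ci_low <= a * b && a * b <= med$ci_high)
    bms <- c(bms, med$bm)
  }
  list(coverage = mean(covered), mean_bm = mean(bms), n_rep = length(covered))
}

#' Type-I error versus sample overlap under a confounded null
#'
#' The regime where two-sample MR is vulnerable to overlap: deliberately
#' weak instruments (mean F around 10-20, selected at a relaxed threshold)
#' and a strong shared confounder of exposure and outcome, with no causal
#' effect anywhere.  As the exposure and outcome GWAS share more
#' individuals, correlated estimation errors push the IVW estimate toward
#' the confounded observational association and inflate the type-I error.
#'
#' @param overlaps Overlap proportions to compare (default `c(0, 0.5, 1)`).
#' @param n_rep Replicates per overlap level (default 100).
#' @param n_snps Instrument SNPs (default 60).
#' @param n_per_gwas Individuals per trait GWAS (default 3000).
#' @param p_threshold Instrument selection threshold (default 1e-3; at
#'   genome-wide stringency this weak-instrument regime selects nothing).
#' @param confound_x,confound_y Confounder loadings (defaults 0.8 and 3).
#' @param alpha Test level (default 0.05).
#' @param seed Experiment seed.
#' @return List with `overlap`, `type1` (rejection rate per level),
#'   `mean_f` (mean instrument F), and `n_rep` per level.
#' @export
experiment_overlap_type1 <- function(overlaps = c(0, 0.5, 1), n_rep = 100,
                                     n_snps = 60, n_per_gwas = 3000,
                                     p_threshold = 1e-3,
                                     confound_x = 0.8, confound_y = 3,
                                     alpha = 0.05, seed = 1) {
  type1 <- mean_f <- n_eff <- numeric(length(overlaps))
  for (k in seq_along(overlaps)) {
    rej <- logical(0)
    fs <- numeric(0)
    for (i in seq_len(n_rep)) {
      cfg <- sim_config(n_snps = n_snps, n_snps_mediator = 0,
                        n_per_gwas = n_per_gwas,
                        effect_x_to_m = 0, effect_m_to_y = 0,
                        direct_x_to_y = 0,
                        confound_x = confound_x, confound_y = confound_y,
                        overlap_prop = overlaps[k], outcome_prevalence = 0.5,
                        seed = child_seed(seed, 1000 * k + i))
      trip <- suppressMessages(make_three_gwas(cfg))
      h <- select_instruments_h(trip$exposure, trip$outcome, p_threshold)
      if (nrow(h) < 3) next
      rej <- c(rej, mr_ivw(h, model = "fixed")$pval < alpha)
      fs <- c(fs, mean((h$beta_x / h$se_x)^2))
    }
    type1[k] <- mean(rej)
    mean_f[k] <- mean(fs)
    n_eff[k] <- length(rej)
  }
  list(overlap = overlaps, type1 = type1, mean_f = mean_f, n_rep = n_eff)
}
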