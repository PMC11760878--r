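#' @title Synthetic GWAS cohorts and summary statistics
#' @description
#' Generates individual-level cohorts with the causal structure the
#' mediation analysis assumes (SNPs -> exposure -> mediator -> binary
#' outcome), plus configurable violations: direct exposure-to-outcome
#' effects, horizontal pleiotropy (SNP -> mediator and SNP -> outcome
#' paths), a shared latent confounder, and partial sample overlap between
#' the exposure and outcome GWAS.  Summary statistics are produced either
#' by per-SNP regression scans of the cohort (the realistic route) or
#' directly from the asymptotic sampling distributions (the fast route used
#' for large calibration studies).
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Exposure and mediator are quantitative with unit variance in
#' expectation; the outcome is binary, generated by thresholding a
#' liability with standard-logistic noise so that `effect_m_to_y` and
#' `direct_x_to_y` are exact conditional log-odds per unit of mediator and
#' exposure.  The SNP panel holds `n_snps` exposure instruments and
#' `n_snps_mediator` mediator instruments (disjoint, independent,
#' biallelic); pleiotropy knobs act on the exposure instruments.
#'
#' @param n_snps Number of exposure-instrument SNPs (default 50).
#' @param n_snps_mediator Number of mediator-instrument SNPs (default
#'   `n_snps`).
#' @param n_per_gwas Individuals per trait GWAS (default 20000).
#' @param maf_range Minor-allele-frequency range (default `c(0.05, 0.5)`).
#' @param gamma_sd SD of the per-SNP effects on the exposure (default 0.09,
#'   about 15% exposure heritability over 50 SNPs).
#' @param alpha_sd SD of the mediator-instrument effects on the mediator
#'   (default 0.09).
#' @param effect_x_to_m Causal effect `a` of exposure on mediator
#'   (default 0.3).
#' @param effect_m_to_y Causal log-odds effect `b` of mediator on outcome
#'   (default 0.4).
#' @param direct_x_to_y Direct log-odds effect `c'` of exposure on outcome
#'   (default 0).
#' @param pleiotropy_frac Fraction of exposure SNPs with direct SNP ->
#'   outcome effects (default 0).
#' @param pleiotropy_sd,pleiotropy_mean Scale and mean of those direct
#'   effects (mean 0 = balanced, non-zero = directional pleiotropy).
#' @param mediator_pleiotropy_frac,mediator_pleiotropy_sd Fraction and scale
#'   of direct exposure-SNP -> mediator effects.
#' @param confound_x,confound_y Loadings of a shared standard-normal latent
#'   confounder on the exposure and on the outcome liability (default 0).
#' @param overlap_prop Proportion of shared individuals between the exposure
#'   and outcome GWAS (default 0).
#' @param outcome_prevalence Outcome prevalence (default 0.1).
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50, n_snps_mediator = n_snps,
                       n_per_gwas = 20000, maf_range = c(0.05, 0.5),
                       gamma_sd = 0.09, alpha_sd = 0.09,
                       effect_x_to_m = 0.3, effect_m_to_y = 0.4,
                       direct_x_to_y = 0,
                       pleiotropy_frac = 0, pleiotropy_sd = 0,
                       pleiotropy_mean = 0,
                       mediator_pleiotropy_frac = 0, mediator_pleiotropy_sd = 0,
                       confound_x = 0, confound_y = 0,
                       overlap_prop = 0, outcome_prevalence = 0.1,
                       seed) {
  if (missing(seed) || is.null(seed)) stopf("sim_config: seed is mandatory")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] >= maf_range[2])
    stopf("maf_range must satisfy 0 < low < high <= 0.5")
  for (p in c(pleiotropy_frac, mediator_pleiotropy_frac, overlap_prop))
    if (p < 0 || p > 1) stopf("fractions must lie in [0, 1]")
  if (outcome_prevalence <= 0 || outcome_prevalence >= 1)
    stopf("outcome_prevalence must lie in (0, 1)")
  structure(as.list(environment()), class = "sim_config")
}

# Draw the per-SNP truth (panel layout, effects, pleiotropy) for a config.
# Must be called inside with_seed().
draw_truth <- function(cfg) {
  m <- cfg$n_snps + cfg$n_snps_mediator
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  is_exp <- seq_len(m) <= cfg$n_snps
  gamma <- ifelse(is_exp, stats::rnorm(m, 0, cfg$gamma_sd), 0)
  alpha_own <- ifelse(is_exp, 0, stats::rnorm(m, 0, cfg$alpha_sd))
  alpha_pleio <- ifelse(
    is_exp & stats::runif(m) < cfg$mediator_pleiotropy_frac,
    stats::rnorm(m, 0, cfg$mediator_pleiotropy_sd), 0)
  # directional pleiotropy is defined relative to the exposure-increasing
  # allele (otherwise the arbitrary allele coding would cancel its mean)
  delta <- ifelse(is_exp & stats::runif(m) < cfg$pleiotropy_frac,
                  sign(gamma) *
                    stats::rnorm(m, cfg$pleiotropy_mean, cfg$pleiotropy_sd), 0)
  # non-palindromic allele pairs so harmonization is letter-resolvable
  pair <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"), ncol = 2,
                 byrow = TRUE)[sample.int(4, m, replace = TRUE), , drop = FALSE]
  # spread SNPs across 22 chromosomes, 20 Mb apart within a chromosome, so
  # they stay independent under distance-only clumping at the default window
  list(variant_id = sprintf("snp_%04d", seq_len(m)),
       chrom = as.character(((seq_len(m) - 1L) %% 22L) + 1L),
       pos = 1L + ((seq_len(m) - 1L) %/% 22L) * 20000000L,
       effect_allele = pair[, 1], other_allele = pair[, 2],
       maf = maf, is_exposure_snp = is_exp,
       gamma = gamma, alpha = alpha_own + alpha_pleio, delta = delta,
       a = cfg$effect_x_to_m, b = cfg$effect_m_to_y,
       c_prime = cfg$direct_x_to_y,
       mediated_effect = cfg$effect_x_to_m * cfg$effect_m_to_y)
}

#' Simulate an individual-level cohort
#'
#' Dosages are binomial(2, maf) per SNP; the exposure and mediator are
#' linear in the dosages plus the latent confounder, with noise variances
#' set so both traits have unit variance in expectation; the binary outcome
#' thresholds a liability with standard-logistic noise at the configured
#' prevalence, making the liability coefficients exact conditional
#' log-odds.  The cohort is large enough to carve out the three trait GWAS
#' subsamples at the configured overlap.  Fully reproducible from the
#' config seed.
#'
#' @param config A [sim_config].
#' @return List with `cohort` (list: `genotypes`, `exposure`, `mediator`,
#'   `outcome`, `snps` metadata data frame) and `truth` (per-SNP effects and
#'   the path coefficients, including `mediated_effect = a*b`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    truth <- draw_truth(config)
    n <- config$n_per_gwas
    n_total <- 3L * n - round(config$overlap_prop * n)
    m <- length(truth$maf)
    vg <- 2 * truth$maf * (1 - truth$maf)

    var_gen_x <- sum(truth$gamma^2 * vg)
    var_eps_x <- 1 - var_gen_x - config$confound_x^2
    if (var_eps_x < -1e-12)
      stopf("infeasible variance budget for exposure (genetic + confounder variance > 1)")
    var_sig_m <- config$effect_x_to_m^2 +
      sum(truth$alpha^2 * vg) +
      2 * config$effect_x_to_m * sum(truth$gamma * truth$alpha * vg)
    var_eps_m <- 1 - var_sig_m
    if (var_eps_m < -1e-12)
      stopf("infeasible variance budget for mediator (signal variance > 1)")
    var_eps_x <- max(0, var_eps_x)
    var_eps_m <- max(0, var_eps_m)

    G <- matrix(stats::rbinom(n_total * m, 2L, rep(truth$maf, each = n_total)),
                nrow = n_total, ncol = m,
                dimnames = list(NULL, truth$variant_id))
    U <- stats::rnorm(n_total)
    X <- drop(G %*% truth$gamma) + config$confound_x * U +
      stats::rnorm(n_total, 0, sqrt(var_eps_x))
    M <- config$effect_x_to_m * X + drop(G %*% truth$alpha) +
      stats::rnorm(n_total, 0, sqrt(var_eps_m))
    liability <- config$direct_x_to_y * X + config$effect_m_to_y * M +
      drop(G %*% truth$delta) + config$confound_y * U +
      stats::rlogis(n_total)
    thr <- stats::quantile(liability, 1 - config$outcome_prevalence,
                           names = FALSE)
    Y <- as.integer(liability > thr)

    snps <- data.frame(variant_id = truth$variant_id, chrom = truth$chrom,
                       pos = truth$pos, effect_allele = truth$effect_allele,
                       other_allele = truth$other_allele, maf = truth$maf,
                       stringsAsFactors = FALSE)
    list(cohort = list(genotypes = G, exposure = X, mediator = M,
                       outcome = Y, snps = snps),
         truth = truth)
  })
}

#' Per-SNP association scan of a cohort
#'
#' Simple linear regression per SNP for quantitative traits (closed form),
#' logistic regression for the binary outcome.  Monomorphic SNPs in the
#' subsample yield missing effects and are dropped by the summary-table
#' validator with a logged count.
#'
#' @param cohort Cohort list from [simulate_cohort()].
#' @param trait `"exposure"`, `"mediator"` or `"outcome"`.
#' @param subsample_ids Row indices of the individuals forming this GWAS
#'   (default all).
#' @param trait_id Label for the resulting table (default the trait name).
#' @return A [summary_table] with per-SNP `beta`, `se`, `pval`, `eaf`, `n`.
#' @export
gwas_scan <- function(cohort, trait = c("exposure", "mediator", "outcome"),
                      subsample_ids = NULL, trait_id = NULL) {
  trait <- match.arg(trait)
  y_all <- cohort[[trait]]
  if (is.null(subsample_ids)) subsample_ids <- seq_along(y_all)
  if (max(subsample_ids) > length(y_all))
    stopf("subsample_ids outside the simulated cohort")
  G <- cohort$genotypes[subsample_ids, , drop = FALSE]
  y <- y_all[subsample_ids]
  n <- length(y)
  m <- ncol(G)
  eaf <- colMeans(G) / 2

  if (trait == "outcome") {
    beta <- se <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      g <- G[, j]
      if (stats::var(g) < .Machine$double.eps) next
      fit <- tryCatch(
        stats::glm.fit(cbind(1, g), y, family = stats::binomial()),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit) || !fit$converged) {
        fit <- tryCatch(
          suppressWarnings(stats::glm.fit(cbind(1, g), y,
                                          family = stats::binomial())),
          error = function(e) NULL)
        if (is.null(fit)) next
      }
      covm <- chol2inv(qr.R(fit$qr))
      beta[j] <- fit$coefficients[2]
      se[j] <- sqrt(covm[2, 2])
    }
    # clamp underflowed tails: a literal zero would fail record validation
    pval <- pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)
  } else {
    gbar <- colMeans(G)
    sxx <- colSums(G^2) - n * gbar^2
    yc <- y - mean(y)
    sxy <- drop(crossprod(G, yc))
    syy <- sum(yc^2)
    mono <- sxx < .Machine$double.eps
    sxx[mono] <- NA_real_
    beta <- sxy / sxx
    sigma2 <- pmax(syy - beta * sxy, 0) / (n - 2)
    se <- sqrt(sigma2 / sxx)
    pval <- pmax(2 * stats::pt(-abs(beta / se), df = n - 2), 1e-300)
  }

  df <- cohort$snps
  df$eaf <- eaf
  df$beta <- beta
  df$se <- se
  df$pval <- pval
  df$n <- n
  summary_table(df, trait_id = trait_id %||% trait,
                trait_type = if (trait == "outcome") "binary" else "quantitative")
}

#' Simulate a three-trait GWAS triplet from one cohort
#'
#' Draws the exposure, outcome and mediator GWAS subsamples (the exposure
#' and outcome samples share `overlap_prop` of their individuals; the
#' mediator sample is disjoint from both) and scans each trait.
#'
#' @param config A [sim_config].
#' @return List with `exposure`, `mediator`, `outcome` (each a
#'   [summary_table]), `truth`, and `subsamples` (the index sets used).
#' @export
make_three_gwas <- function(config) {
  sim <- simulate_cohort(config)
  n <- config$n_per_gwas
  o <- round(config$overlap_prop * n)
  n_total <- nrow(sim$cohort$genotypes)
  if (3L * n - o > n_total)
    stopf("overlap_prop demands more individuals than simulated")
  ids_x <- seq_len(n)
  ids_y <- seq.int(n - o + 1L, 2L * n - o)
  ids_m <- seq.int(2L * n - o + 1L, 3L * n - o)
  list(exposure = gwas_scan(sim$cohort, "exposure", ids_x),
       mediator = gwas_scan(sim$cohort, "mediator", ids_m),
       outcome = gwas_scan(sim$cohort, "outcome", ids_y),
       truth = sim$truth,
       subsamples = list(exposure = ids_x, mediator = ids_m, outcome = ids_y),
       cohort = sim$cohort)
}

#' Fast summary-level GWAS triplet from asymptotic sampling distributions
#'
#' Draws the three summary tables directly: each estimated effect is normal
#' around its true marginal value with the asymptotic standard error
#' (`1/sqrt(n vg)` for unit-variance quantitative traits,
#' `1/sqrt(n p(1-p) vg)` on the log-odds scale for the binary outcome,
#' `vg = 2 maf (1-maf)`).  Requires independent samples (no overlap, no
#' confounding); used for large replicate calibration studies where
#' individual-level simulation would be needlessly slow.
#'
#' @param config A [sim_config] with `overlap_prop = 0`,
#'   `confound_x = confound_y = 0`.
#' @return List with `exposure`, `mediator`, `outcome` tables and `truth`.
#' @export
simulate_summary_gwas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$overlap_prop != 0 || config$confound_x != 0 || config$confound_y != 0)
    stopf("summary-level route requires overlap_prop = 0 and no confounding; use make_three_gwas()")
  with_seed(config$seed, {
    truth <- draw_truth(config)
    n <- config$n_per_gwas
    vg <- 2 * truth$maf * (1 - truth$maf)
    prev <- config$outcome_prevalence

    bx_true <- truth$gamma
    bm_true <- truth$a * truth$gamma + truth$alpha
    by_true <- (truth$c_prime + truth$a * truth$b) * truth$gamma +
      truth$b * truth$alpha + truth$delta

    one_table <- function(true, se, trait_id, trait_type) {
      beta <- stats::rnorm(length(true), true, se)
      df <- data.frame(variant_id = truth$variant_id, chrom = truth$chrom,
                       pos = truth$pos, effect_allele = truth$effect_allele,
                       other_allele = truth$other_allele, eaf = truth$maf,
                       beta = beta, se = se,
                       pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
                       n = n,
                       stringsAsFactors = FALSE)
      summary_table(df, trait_id = trait_id, trait_type = trait_type)
    }
    list(exposure = one_table(bx_true, 1 / sqrt(n * vg), "exposure",
                              "quantitative"),
         mediator = one_table(bm_true, 1 / sqrt(n * vg), "mediator",
                              "quantitative"),
         outcome = one_table(by_true, 1 / sqrt(n * prev * (1 - prev) * vg),
                             "outcome", "binary"),
         truth = truth)
  })
}

#' Write a simulated GWAS triplet to disk
#'
#' Writes the three summary tables in the package TSV dialect plus the
#' ground truth as JSON.
#'
#' @param triplet Result of [make_three_gwas()] or
#'   [simulate_summary_gwas()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_gwas_triplet <- function(triplet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(triplet$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(triplet$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(triplet$outcome, file.path(dir, "outcome.tsv"))
  jsonlite::write_json(triplet$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
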