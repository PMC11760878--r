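#' @title Sensitivity diagnostics for two-sample MR
#' @description
#' Heterogeneity (Cochran's Q), directional pleiotropy (Egger intercept),
#' outlying pleiotropic instruments (MR-PRESSO), directionality (Steiger),
#' and the expected bias from overlapping exposure/outcome samples.
#' @name diagnostics
NULL

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (r_j - b)^2` over the Wald ratios with inverse-variance
#' weights, compared to a chi-square distribution on k-1 degrees of freedom.
#'
#' @param h A `harmonized_table` with at least 2 pairs.
#' @param b Reference causal estimate; defaults to the fixed-effects IVW
#'   estimate.
#' @return List with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(h, b = NULL) {
  wr <- wald_ratios(h)
  k <- nrow(wr)
  if (k < 2) stopf("Cochran's Q needs at least 2 variants, got %d", k)
  w <- 1 / wr$ratio_se^2
  if (is.null(b)) b <- sum(w * wr$ratio) / sum(w)
  Q <- sum(w * (wr$ratio - b)^2)
  list(Q = Q, df = k - 1,
       pval = stats::pchisq(Q, df = k - 1, lower.tail = FALSE))
}

#' Egger intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression with its standard error and
#' two-sided p-value; a non-zero intercept indicates directional horizontal
#' pleiotropy (judged at p < 0.05).
#'
#' @param h A `harmonized_table` with at least 3 pairs.
#' @return List with `intercept`, `se`, `pval`, `significant`.
#' @export
egger_intercept_test <- function(h) {
  it <- mr_egger(h)$intercept
  list(intercept = it$estimate, se = it$se, pval = it$pval,
       significant = it$pval < 0.05)
}

#' MR-PRESSO outlier test
#'
#' Residual-sum-of-squares test for pleiotropic outliers.  For each variant
#' j the leave-one-out IVW slope `b(-j)` predicts its outcome effect; the
#' observed global RSS is `sum_j (beta_y_j - b(-j) beta_x_j)^2`.  The null
#' distribution is simulated by drawing `beta_x_j* ~ N(beta_x_j, se_x_j)`
#' and `beta_y_j* ~ N(b(-j) beta_x_j, se_y_j)` `n_sim` times and
#' recomputing the leave-one-out slopes and RSS within each simulated
#' dataset, so the null RSS carries the same slope-estimation noise as the
#' observed one; the global p-value is the fraction of simulated RSS
#' values at or above the observed one.  Per-variant p-values are the
#' analogous tail fractions of each squared term, and variants significant
#' at the Bonferroni level `outlier_alpha / k` are flagged as outliers.
#'
#' @param h A `harmonized_table` with at least 4 pairs.
#' @param n_sim Number of simulated datasets (default 1000).
#' @param outlier_alpha Family-wise level for outlier flagging (default 0.05).
#' @param seed Simulation seed (default 1).
#' @return List of class `mr_presso` with `global_rss`, `global_pval`,
#'   `per_snp_pvals` (named), `outlier_ids`, `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  k <- nrow(h)
  if (k < 4) stopf("MR-PRESSO needs at least 4 variants, got %d", k)
  bx <- h$beta_x; by <- h$beta_y; sy <- h$se_y
  w <- 1 / sy^2
  # leave-one-out IVW (origin-constrained WLS) slopes via totals
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  b_loo <- (sxy - w * bx * by) / (sxx - w * bx^2)
  mu <- b_loo * bx
  obs_terms <- (by - mu)^2
  obs_rss <- sum(obs_terms)

  with_seed(seed, {
    bx_sim <- matrix(stats::rnorm(n_sim * k, mean = rep(bx, each = n_sim),
                                  sd = rep(h$se_x, each = n_sim)),
                     nrow = n_sim, ncol = k)
    by_sim <- matrix(stats::rnorm(n_sim * k, mean = rep(mu, each = n_sim),
                                  sd = rep(sy, each = n_sim)),
                     nrow = n_sim, ncol = k)
    # leave-one-out slopes recomputed within each simulated dataset
    wm <- matrix(w, n_sim, k, byrow = TRUE)
    sxy_sim <- (wm * bx_sim * by_sim) %*% matrix(1, k, 1)
    sxx_sim <- (wm * bx_sim^2) %*% matrix(1, k, 1)
    b_loo_sim <- (drop(sxy_sim) - wm * bx_sim * by_sim) /
      (drop(sxx_sim) - wm * bx_sim^2)
    sim_terms <- (by_sim - b_loo_sim * bx_sim)^2
    sim_rss <- rowSums(sim_terms)
    global_pval <- mean(sim_rss >= obs_rss)
    per_snp <- colMeans(sweep(sim_terms, 2, obs_terms, ">="))
  })
  per_snp <- stats::setNames(per_snp, h$variant_id)
  outliers <- names(per_snp)[per_snp < outlier_alpha / k]
  structure(list(global_rss = obs_rss, global_pval = global_pval,
                 per_snp_pvals = per_snp, outlier_ids = outliers,
                 n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.4g, global p = %.4g (%d sims)\n",
              x$global_rss, x$global_pval, x$n_sim))
  if (length(x$outlier_ids))
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  else cat("  no outliers detected\n")
  invisible(x)
}

#' Remove MR-PRESSO outliers from a harmonized table
#'
#' @param h A `harmonized_table`.
#' @param presso An [mr_presso] result (or character vector of variant ids).
#' @return The table without the flagged variants; removed ids in the
#'   `"presso_outliers"` attribute.
#' @export
remove_outliers <- function(h, presso) {
  ids <- if (inherits(presso, "mr_presso")) presso$outlier_ids else presso
  out <- h[!h$variant_id %in% ids, , drop = FALSE]
  attr(out, "presso_outliers") <- intersect(ids, h$variant_id)
  out
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure against the
#' variance they explain in the outcome.  Per-variant r-squared is obtained
#' from the F approximation `r2 = F/(F + n - 2)` and summed over
#' instruments on each side; the direction is called correct when the
#' exposure r-squared exceeds the outcome r-squared.  The p-value is a
#' two-sample z-test on the Fisher-transformed correlations `r = sqrt(r2)`.
#' For binary outcomes the same approximation is applied on the log-odds
#' scale.
#'
#' @param h A `harmonized_table`.
#' @param n_exposure,n_outcome GWAS sample sizes; default to the median of
#'   the per-variant `n_x`/`n_y` columns when present.
#' @return List with `r2_exposure`, `r2_outcome`, `correct_direction`,
#'   `pval`.
#' @export
steiger <- function(h, n_exposure = NULL, n_outcome = NULL) {
  n_exposure <- n_exposure %||%
    (if (!all(is.na(h$n_x))) stats::median(h$n_x, na.rm = TRUE) else NULL)
  n_outcome <- n_outcome %||%
    (if (!all(is.na(h$n_y))) stats::median(h$n_y, na.rm = TRUE) else NULL)
  if (is.null(n_exposure)) stopf("steiger: exposure sample size unknown")
  if (is.null(n_outcome)) stopf("steiger: outcome sample size unknown")
  r2_one <- function(beta, se, n) {
    f <- (beta / se)^2
    sum(f / (f + n - 2))
  }
  r2x <- r2_one(h$beta_x, h$se_x, n_exposure)
  r2y <- r2_one(h$beta_y, h$se_y, n_outcome)
  r2x <- min(r2x, 0.999); r2y <- min(r2y, 0.999)
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  list(r2_exposure = r2x, r2_outcome = r2y,
       correct_direction = r2x > r2y, pval = 2 * stats::pnorm(-abs(z)))
}

#' Expected bias and type-I error from sample overlap
#'
#' For two-sample MR with a proportion of shared participants, the expected
#' bias of the causal estimate is approximately the overlap proportion times
#' the confounded (observational) effect divided by the mean instrument
#' F-statistic.  The induced type-I error is the probability that a standard
#' normal shifted by `bias/se_unit` exceeds the two-sided critical value.
#'
#' @param mean_f Mean instrument F-statistic (> 0).
#' @param overlap_prop Proportion of overlapping participants in `[0, 1]`.
#' @param assumed_confounded_effect Observational (confounded) association
#'   between exposure and outcome.
#' @param alpha Nominal level (default 0.05).
#' @param se_unit Null standard-error scale of the causal estimate
#'   (default 1 bias unit).
#' @return List with `overlap_prop`, `mean_f`, `assumed_confounded_effect`,
#'   `expected_bias`, `type1_error`.
#' @export
overlap_bias <- function(mean_f, overlap_prop, assumed_confounded_effect,
                         alpha = 0.05, se_unit = 1) {
  if (mean_f <= 0) stopf("mean_f must be positive")
  if (overlap_prop < 0 || overlap_prop > 1) stopf("overlap_prop must be in [0, 1]")
  bias <- overlap_prop * assumed_confounded_effect / mean_f
  zc <- stats::qnorm(1 - alpha / 2)
  shift <- bias / se_unit
  type1 <- stats::pnorm(-zc - shift) + stats::pnorm(-(zc - shift))
  list(overlap_prop = overlap_prop, mean_f = mean_f,
       assumed_confounded_effect = assumed_confounded_effect,
       expected_bias = bias, type1_error = type1)
}

#' Full sensitivity panel for one analysis direction
#'
#' Bundles Cochran's Q, the Egger intercept test, MR-PRESSO (when at least 4
#' variants are available) and the Steiger test (when sample sizes are
#' known) into one flat row, plus the per-variant ratio table used for
#' scatter/funnel rendering.
#'
#' @param h A `harmonized_table`.
#' @param n_sim MR-PRESSO simulations (default 1000).
#' @param seed Seed for MR-PRESSO (default 1).
#' @return List with `Q`, `Q_df`, `Q_pval`, `egger_intercept`, `egger_se`,
#'   `egger_pval`, `presso_global_pval`, `n_outliers`, `steiger_direction`,
#'   `steiger_pval`, and `per_snp` (data frame `variant_id`, `ratio`, `se`).
#' @export
mr_sensitivity <- function(h, n_sim = 1000, seed = 1) {
  q <- cochran_q(h)
  eg <- egger_intercept_test(h)
  pr <- if (nrow(h) >= 4) mr_presso(h, n_sim = n_sim, seed = seed) else NULL
  st <- tryCatch(steiger(h), error = function(e) NULL)
  wr <- wald_ratios(h)
  list(Q = q$Q, Q_df = q$df, Q_pval = q$pval,
       egger_intercept = eg$intercept, egger_se = eg$se, egger_pval = eg$pval,
       presso_global_pval = if (is.null(pr)) NA_real_ else pr$global_pval,
       n_outliers = if (is.null(pr)) NA_integer_ else length(pr$outlier_ids),
       steiger_direction = if (is.null(st)) NA else st$correct_direction,
       steiger_pval = if (is.null(st)) NA_real_ else st$pval,
       per_snp = data.frame(variant_id = wr$variant_id, ratio = wr$ratio,
                            se = wr$ratio_se, stringsAsFactors = FALSE))
}
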