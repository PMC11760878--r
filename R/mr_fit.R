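#' @title Two-sample MR estimators
#' @description
#' Five estimators of the causal effect of an exposure on an outcome from
#' harmonized per-variant effect pairs: inverse-variance weighted (IVW),
#' MR-Egger, weighted median, and the simple and weighted mode.  All share
#' the per-variant Wald ratio as the basic ingredient; p-values are
#' two-sided normal throughout, and estimates on the log-odds scale are
#' reported alongside their odds-ratio transform `OR = exp(B)` with
#' `exp(B -/+ 1.96 SE)` confidence limits.
#' @name mr_estimators
NULL

#' Per-variant Wald ratios
#'
#' The ratio estimate `beta_y / beta_x` with first-order (delta-method)
#' standard error `se_y / |beta_x|`.  Pairs with `beta_x == 0` are excluded
#' with a warning.
#'
#' @param h A `harmonized_table`.
#' @return Data frame with `variant_id`, `ratio`, `ratio_se`.
#' @export
wald_ratios <- function(h) {
  zero <- h$beta_x == 0
  if (any(zero)) {
    warnf("excluding %d pair(s) with beta_x = 0 from Wald ratios", sum(zero))
    h <- h[!zero, , drop = FALSE]
  }
  data.frame(variant_id = h$variant_id,
             ratio = h$beta_y / h$beta_x,
             ratio_se = h$se_y / abs(h$beta_x),
             stringsAsFactors = FALSE)
}

mr_estimate <- function(method, b, se, n_snps, model = NA_character_) {
  data.frame(method = method, b = b, se = se, pval = z_pval(b, se),
             or = exp(b), ci_low = exp(b - 1.96 * se),
             ci_high = exp(b + 1.96 * se), n_snps = n_snps, model = model,
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate
#'
#' Precision-weighted mean of the Wald ratios with weights `1/ratio_se^2`.
#' The fixed-effects standard error is `(sum w)^(-1/2)`; the
#' (multiplicative) random-effects model inflates it by
#' `max(1, sqrt(Q/(k-1)))` where Q is Cochran's heterogeneity statistic.
#' Under `model = "auto"` the random-effects model is used when the Q test
#' has p < 0.05, otherwise fixed effects.
#'
#' @param h A `harmonized_table` with at least 2 pairs.
#' @param model `"auto"` (default), `"fixed"` or `"random"`.
#' @return One-row estimate data frame (method `"ivw"`); attributes `Q`,
#'   `Q_df`, `Q_pval` carry the heterogeneity test.
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  wr <- wald_ratios(h)
  k <- nrow(wr)
  if (k < 2) stopf("IVW needs at least 2 variants, got %d", k)
  w <- 1 / wr$ratio_se^2
  b <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  Q <- sum(w * (wr$ratio - b)^2)
  q_pval <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  used <- switch(model,
                 fixed = "fixed",
                 random = "random",
                 auto = if (q_pval < 0.05) "random" else "fixed")
  se <- if (used == "random") se_fixed * max(1, sqrt(Q / (k - 1))) else se_fixed
  out <- mr_estimate("ivw", b, se, k, model = used)
  attr(out, "Q") <- Q
  attr(out, "Q_df") <- k - 1
  attr(out, "Q_pval") <- q_pval
  out
}

# Weighted least squares of y on (1, x): coefficients, unscaled covariance
# and weighted RSS, via the normal equations.
wls_fit <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * y)
  coefs <- drop(solve(XtWX, XtWy))
  fitted <- drop(X %*% coefs)
  rss_w <- sum(w * (y - fitted)^2)
  list(coef = coefs, cov_unscaled = solve(XtWX), rss_w = rss_w,
       fitted = fitted)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept, weights `1/se_y^2`, after orienting every pair so that
#' `beta_x >= 0`.  The slope is the causal estimate; a non-zero intercept
#' indicates directional horizontal pleiotropy.  Standard errors use
#' multiplicative residual inflation `max(1, sqrt(RSS_w/(k-2)))`.
#'
#' @param h A `harmonized_table` with at least 3 pairs.
#' @return List with `slope` (one-row estimate data frame, method
#'   `"egger"`) and `intercept` (list with `estimate`, `se`, `pval`).
#' @export
mr_egger <- function(h) {
  k <- nrow(h)
  if (k < 3) stopf("MR-Egger needs at least 3 variants, got %d", k)
  flip <- sign(h$beta_x) < 0
  bx <- abs(h$beta_x)
  by <- ifelse(flip, -h$beta_y, h$beta_y)
  w <- 1 / h$se_y^2
  fit <- wls_fit(bx, by, w)
  sigma <- sqrt(fit$rss_w / (k - 2))
  infl <- max(1, sigma)
  ses <- sqrt(diag(fit$cov_unscaled)) * infl
  slope <- mr_estimate("egger", fit$coef[2], ses[2], k)
  intercept <- list(estimate = unname(fit$coef[1]), se = unname(ses[1]),
                    pval = z_pval(fit$coef[1], ses[1]))
  list(slope = slope, intercept = intercept)
}

# Weighted median of values `b` with weights `w`: linear interpolation of
# the cumulative standardized weights (midpoint convention) at 0.5.
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(b[1])
  k <- length(b)
  if (cum[k] <= 0.5) return(b[k])
  j <- max(which(cum < 0.5))
  b[j] + (b[j + 1] - b[j]) * (0.5 - cum[j]) / (cum[j + 1] - cum[j])
}

# Parametric bootstrap over the sampling distribution of the summary
# effects; `point_fun(bx, by)` recomputes the estimator.
boot_se <- function(h, point_fun, n_boot, seed) {
  with_seed(seed, {
    k <- nrow(h)
    ests <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, h$beta_x, h$se_x)
      by <- stats::rnorm(k, h$beta_y, h$se_y)
      point_fun(bx, by)
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted median estimate
#'
#' Orders the Wald ratios and interpolates the cumulative standardized
#' inverse-variance weights at 0.5; consistent when at least half the weight
#' comes from valid instruments.  The standard error is a seeded parametric
#' bootstrap (resampling the summary effects from their sampling
#' distributions).
#'
#' @param h A `harmonized_table` with at least 3 pairs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (default 1).
#' @return One-row estimate data frame (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1) {
  if (nrow(h) < 3) stopf("weighted median needs at least 3 variants, got %d", nrow(h))
  wr <- wald_ratios(h)
  b <- weighted_median_point(wr$ratio, 1 / wr$ratio_se^2)
  se <- boot_se(h, function(bx, by) {
    ok <- bx != 0
    weighted_median_point(by[ok] / bx[ok], (abs(bx[ok]) / h$se_y[ok])^2)
  }, n_boot, seed)
  mr_estimate("weighted_median", b, se, nrow(wr))
}

# Mode of the weighted normal-kernel density of the ratios on a fine grid.
mode_point <- function(ratios, weights, phi) {
  s <- stats::sd(ratios)
  iqr <- stats::IQR(ratios) / 1.349
  bw <- phi * 0.9 * min(s, iqr) * length(ratios)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(ratios[1])  # all ratios identical
  grid <- seq(min(ratios) - 3 * bw, max(ratios) + 3 * bw, length.out = 2048)
  dens <- vapply(grid, function(x)
    sum(weights * stats::dnorm((x - ratios) / bw)), numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The densest point of a normal-kernel density over the Wald ratios, with
#' bandwidth `phi * 0.9 * min(sd, IQR/1.349) * k^(-1/5)`; weights are
#' uniform (simple mode) or inverse-variance (weighted mode).  Consistent
#' when the largest homogeneous cluster of instruments is valid.  SE by
#' seeded parametric bootstrap.
#'
#' @param h A `harmonized_table` with at least 3 pairs.
#' @param weighted Use inverse-variance weights? (`FALSE` = simple mode.)
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (default 1).
#' @return One-row estimate data frame (method `"weighted_mode"` or
#'   `"simple_mode"`).
#' @export
mr_mode <- function(h, weighted = TRUE, phi = 1, n_boot = 1000, seed = 1) {
  if (nrow(h) < 3) stopf("mode estimator needs at least 3 variants, got %d", nrow(h))
  wr <- wald_ratios(h)
  wts <- function(ratio_se) if (weighted) 1 / ratio_se^2 else rep(1, length(ratio_se))
  b <- mode_point(wr$ratio, wts(wr$ratio_se), phi)
  se <- boot_se(h, function(bx, by) {
    ok <- bx != 0
    mode_point(by[ok] / bx[ok], wts(h$se_y[ok] / abs(bx[ok])), phi)
  }, n_boot, seed)
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode", b, se, nrow(wr))
}

#' Causal call from a five-method panel
#'
#' The decision rules applied to each analysis direction: (1) the five
#' effect estimates must be directionally consistent (all positive or all
#' negative); (2) significance is judged by the IVW p-value at 0.05, with no
#' multiple-testing correction; (3) a significant effect is classed as a
#' risk factor when OR > 1 and protective when OR < 1.
#'
#' @param estimates Data frame of the five method estimates (columns
#'   `method`, `b`, `pval`), or an [mr_fit] object.
#' @param alpha Significance level for the IVW p-value (default 0.05).
#' @return List with `directionally_consistent`, `p_ivw`, `significant`,
#'   and `direction` (`"risk"`, `"protective"` or `"null"`).
#' @export
causal_call <- function(estimates, alpha = 0.05) {
  if (inherits(estimates, "mr_fit")) estimates <- estimates$estimates
  if (!"ivw" %in% estimates$method) stopf("panel has no IVW estimate")
  consistent <- all(estimates$b > 0) || all(estimates$b < 0)
  p_ivw <- estimates$pval[estimates$method == "ivw"]
  b_ivw <- estimates$b[estimates$method == "ivw"]
  significant <- consistent && p_ivw < alpha
  direction <- if (!significant) "null" else if (b_ivw > 0) "risk" else "protective"
  list(directionally_consistent = consistent, p_ivw = p_ivw,
       significant = significant, direction = direction)
}

#' Fit the five two-sample MR estimators
#'
#' The central fitting function: runs IVW, MR-Egger, weighted median, simple
#' mode and weighted mode on a harmonized table, bundles the estimates with
#' the Egger intercept, Cochran's Q and the causal call.
#'
#' @param h A `harmonized_table` with at least 3 pairs.
#' @param model IVW model, `"auto"` (default), `"fixed"` or `"random"`.
#' @param phi Mode-estimator bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates for median/mode SEs (default 1000).
#' @param seed Seed for the bootstraps (default 1).
#' @param alpha Significance level for the causal call (default 0.05).
#' @return An object of class `mr_fit`: list with `estimates` (five-row data
#'   frame with `method`, `b`, `se`, `pval`, `or`, `ci_low`, `ci_high`,
#'   `n_snps`, `model`), `egger_intercept`, `heterogeneity` (`Q`, `df`,
#'   `pval`), `call_rule` (the causal call), `data`, and the settings used.
#' @seealso [causal_call()], [mr_sensitivity()]
#' @examples
#' h <- harmonized_table(data.frame(
#'   beta_x = c(0.12, 0.10, 0.15, 0.09, 0.11),
#'   se_x = 0.01,
#'   beta_y = c(0.060, 0.052, 0.071, 0.047, 0.055),
#'   se_y = 0.02))
#' fit <- mr_fit(h, n_boot = 50, seed = 1)
#' coef(fit)
#' @export
mr_fit <- function(h, model = "auto", phi = 1, n_boot = 1000, seed = 1,
                   alpha = 0.05) {
  if (nrow(h) < 3) stopf("mr_fit needs at least 3 variants, got %d", nrow(h))
  ivw <- mr_ivw(h, model = model)
  egger <- mr_egger(h)
  wm <- mr_weighted_median(h, n_boot = n_boot, seed = child_seed(seed, 1))
  sm <- mr_mode(h, weighted = FALSE, phi = phi, n_boot = n_boot,
                seed = child_seed(seed, 2))
  wmo <- mr_mode(h, weighted = TRUE, phi = phi, n_boot = n_boot,
                 seed = child_seed(seed, 3))
  estimates <- rbind(ivw, egger$slope, wm, sm, wmo)
  rownames(estimates) <- NULL
  out <- list(
    estimates = estimates,
    egger_intercept = egger$intercept,
    heterogeneity = list(Q = attr(ivw, "Q"), df = attr(ivw, "Q_df"),
                         pval = attr(ivw, "Q_pval")),
    call_rule = causal_call(estimates, alpha = alpha),
    data = h,
    settings = list(model = model, phi = phi, n_boot = n_boot, seed = seed,
                    alpha = alpha),
    exposure_id = attr(h, "exposure_id"),
    outcome_id = attr(h, "outcome_id")
  )
  class(out) <- "mr_fit"
  out
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d variants)\n",
              x$exposure_id %||% "exposure", x$outcome_id %||% "outcome",
              x$estimates$n_snps[1]))
  est <- x$estimates
  est[c("b", "se", "or", "ci_low", "ci_high")] <-
    lapply(est[c("b", "se", "or", "ci_low", "ci_high")], signif, digits)
  est$pval <- signif(est$pval, 3)
  print(est, row.names = FALSE)
  cr <- x$call_rule
  cat(sprintf("Causal call: %s (consistent = %s, P_IVW = %.3g)\n",
              cr$direction, cr$directionally_consistent, cr$p_ivw))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$b, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  out <- cbind(est$b - z * est$se, est$b + z * est$se)
  dimnames(out) <- list(est$method,
                        sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  out
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object,
                 sensitivity = mr_sensitivity(object$data,
                                              seed = object$settings$seed)),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  s <- x$sensitivity
  cat(sprintf("Heterogeneity: Q = %.3f (df %d), p = %.3g\n",
              s$Q, s$Q_df, s$Q_pval))
  cat(sprintf("Egger intercept: %.4g (se %.3g), p = %.3g\n",
              s$egger_intercept, s$egger_se, s$egger_pval))
  if (!is.na(s$presso_global_pval))
    cat(sprintf("MR-PRESSO global p = %.3g, %d outlier(s)\n",
                s$presso_global_pval, s$n_outliers))
  if (!is.na(s$steiger_pval))
    cat(sprintf("Steiger: direction %s, p = %.3g\n",
                ifelse(s$steiger_direction, "correct", "reversed"), s$steiger_pval))
  invisible(x)
}

#' Export an estimate panel as a results table
#'
#' Flat table mirroring the forest-plot report columns: exposure, outcome,
#' method, number of SNPs, B, S, P, OR and confidence limits.
#'
#' @param fit An [mr_fit] object.
#' @return Data frame with one row per method.
#' @export
mr_results_table <- function(fit) {
  stopifnot(inherits(fit, "mr_fit"))
  est <- fit$estimates
  data.frame(exposure = fit$exposure_id %||% "exposure",
             outcome = fit$outcome_id %||% "outcome",
             method = est$method, N = est$n_snps, B = est$b, S = est$se,
             P = est$pval, OR = est$or, ci_low = est$ci_low,
             ci_high = est$ci_high, model = est$model,
             stringsAsFactors = FALSE)
}
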