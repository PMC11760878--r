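#' @title Two-step mediation analysis
#' @description
#' The mediation machinery estimates the exposure-to-mediator effect (B1,
#' S1) either by two-stage least squares on an individual-level cohort or by
#' an intercept-including weighted regression on harmonized summary
#' statistics, takes the mediator-to-outcome effect (B2, S2) from the IVW
#' estimator, and combines the two with the product-of-coefficients (Sobel)
#' method: `Bm = B1 B2`, `Sm = sqrt(B1^2 S2^2 + B2^2 S1^2)`, `Z = Bm/Sm`,
#' with a two-sided normal p-value and `Bm +/- 1.96 Sm` confidence limits.
#' @name mediation
NULL

stage_one_result <- function(coefs, mode) {
  structure(c(coefs, list(mode = mode)), class = "stage_one")
}

#' @export
print.stage_one <- function(x, ...) {
  cat(sprintf("Stage 1 (%s): exposure -> mediator\n", x$mode))
  tab <- data.frame(
    Coefficients = c("Intercept", "Predicted"),
    B = signif(c(x$intercept, x$B1), 3),
    S = signif(c(x$intercept_se, x$S1), 3),
    t = round(c(x$intercept_t, x$t), 2),
    P = signif(c(x$intercept_p, x$pval), 3),
    R2 = c(signif(x$r2, 3), ""))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Two-stage least squares on an individual-level cohort
#'
#' Stage A regresses the exposure on the instrument dosages (with
#' intercept); stage B regresses the mediator on the fitted exposure values
#' (with intercept).  Returns the stage-B intercept and slope with standard
#' errors, t statistics and p-values (t distribution, n - 2 df) and the
#' stage-B R-squared.
#'
#' @param cohort A cohort list as produced by [simulate_cohort()]:
#'   `genotypes` (n x m dosage matrix), `exposure`, `mediator` vectors.
#' @param instrument_ids Columns of the genotype matrix to use as
#'   instruments (names or indices); default all.
#' @return A `stage_one` object with fields `intercept`, `intercept_se`,
#'   `intercept_t`, `intercept_p`, `B1`, `S1`, `t`, `pval`, `r2`.
#' @export
two_stage_least_squares <- function(cohort, instrument_ids = NULL) {
  G <- cohort$genotypes
  if (is.null(instrument_ids)) instrument_ids <- seq_len(ncol(G))
  G <- G[, instrument_ids, drop = FALSE]
  n <- nrow(G)
  if (ncol(G) < 1) stopf("2SLS needs at least one instrument")
  if (n <= ncol(G) + 2) stopf("2SLS needs n > n_instruments + 2")
  stage_a <- stats::lm.fit(cbind(1, G), cohort$exposure)
  aliased <- is.na(stage_a$coefficients)
  if (any(aliased[-1])) {
    warnf("dropping %d collinear instrument(s) in stage A", sum(aliased[-1]))
    G <- G[, !aliased[-1], drop = FALSE]
    stage_a <- stats::lm.fit(cbind(1, G), cohort$exposure)
  }
  x_hat <- drop(cbind(1, G) %*% stage_a$coefficients)
  if (stats::var(x_hat) < .Machine$double.eps)
    stopf("singular 2SLS fit: fitted exposure has no variance")
  fit <- stats::lm(cohort$mediator ~ x_hat)
  sm <- summary(fit)
  co <- sm$coefficients
  stage_one_result(list(
    intercept = co[1, 1], intercept_se = co[1, 2], intercept_t = co[1, 3],
    intercept_p = co[1, 4],
    B1 = co[2, 1], S1 = co[2, 2], t = co[2, 3], pval = co[2, 4],
    r2 = sm$r.squared), mode = "individual_2sls")
}

#' Summary-level stage-1 regression (exposure to mediator)
#'
#' Weighted regression of the mediator-side effects on the exposure-side
#' effects, with an intercept, weights `1/se_y^2`, reproducing the stage-1
#' report shape (intercept row, predicted row, t = B/S, p from a
#' t-distribution with k - 2 df, and the weighted regression R-squared).
#'
#' @param h A `harmonized_table` of exposure-instrument effects on exposure
#'   (x side) and mediator (y side), with at least 3 pairs.
#' @return A `stage_one` object (see [two_stage_least_squares()]).
#' @export
summary_stage_one <- function(h) {
  k <- nrow(h)
  if (k < 3) stopf("summary stage 1 needs at least 3 variants, got %d", k)
  w <- 1 / h$se_y^2
  fit <- stats::lm(beta_y ~ beta_x, data = as.data.frame(h), weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  # weighted R2 about the weighted mean
  wbar <- sum(w * h$beta_y) / sum(w)
  r2 <- 1 - sum(w * stats::residuals(fit)^2) / sum(w * (h$beta_y - wbar)^2)
  stage_one_result(list(
    intercept = co[1, 1], intercept_se = co[1, 2], intercept_t = co[1, 3],
    intercept_p = co[1, 4],
    B1 = co[2, 1], S1 = co[2, 2], t = co[2, 3],
    pval = 2 * stats::pt(-abs(co[2, 3]), df = k - 2),
    r2 = r2), mode = "summary_wls")
}

#' Product-of-coefficients (Sobel) mediation
#'
#' Combines the stage-1 effect of the exposure on the mediator with the
#' stage-2 effect of the mediator on the outcome: `Bm = B1 B2` with
#' `Sm = sqrt(B1^2 S2^2 + B2^2 S1^2)`, `Z = Bm / Sm`, a two-sided normal
#' p-value, and 95% confidence limits `Bm +/- 1.96 Sm`.
#'
#' @param b1 Stage-1 effect, or a `stage_one` object (then `s1` is ignored).
#' @param s1 Stage-1 standard error (> 0).
#' @param b2 Stage-2 effect (log-odds per unit mediator), or a one-row IVW
#'   estimate data frame (then `s2` is ignored).
#' @param s2 Stage-2 standard error (> 0).
#' @return An object of class `mr_mediation`: list with `b1`, `s1`, `b2`,
#'   `s2`, `bm`, `sm`, `z`, `pval`, `ci_low`, `ci_high`.
#' @examples
#' # a mediated path: stage-1 effect 0.0837 (SE 0.0131),
#' # stage-2 log-odds log(1.411)
#' sobel_mediation(0.0837, 0.0131, log(1.411), 0.08)
#' @export
sobel_mediation <- function(b1, s1 = NULL, b2, s2 = NULL) {
  if (inherits(b1, "stage_one")) { s1 <- b1$S1; b1 <- b1$B1 }
  if (is.data.frame(b2)) { s2 <- b2$se[1]; b2 <- b2$b[1] }
  if (is.null(s1) || is.null(s2) || s1 <= 0 || s2 <= 0)
    stopf("sobel_mediation needs positive standard errors s1 and s2")
  bm <- b1 * b2
  sm <- sqrt(b1^2 * s2^2 + b2^2 * s1^2)
  z <- bm / sm
  structure(list(b1 = b1, s1 = s1, b2 = b2, s2 = s2,
                 bm = bm, sm = sm, z = z, pval = 2 * stats::pnorm(-abs(z)),
                 ci_low = bm - 1.96 * sm, ci_high = bm + 1.96 * sm),
            class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat("Product-of-coefficients (Sobel) mediation\n")
  cat(sprintf("  B1 = %.4g (S1 = %.3g), B2 = %.4g (S2 = %.3g)\n",
              x$b1, x$s1, x$b2, x$s2))
  cat(sprintf("  Bm = %.4g, Sm = %.4g, Z = %.3f, Pm = %.3g\n",
              x$bm, x$sm, x$z, x$pval))
  cat(sprintf("  95%% CI: [%.4g, %.4g]\n", x$ci_low, x$ci_high))
  invisible(x)
}
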