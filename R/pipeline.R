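#' @title Full two-step MR mediation pipeline
#' @description
#' Orchestrates the whole workflow over configured exposure / mediator /
#' outcome triplets: instrument selection and QC per direction, the
#' five-estimator panel with causal calls, sensitivity diagnostics, the
#' stage-1 exposure-to-mediator fit, the stage-2 IVW mediator-to-outcome
#' fit, and the Sobel mediation for every exposure-outcome pair, with a
#' complete audit log of instrument attrition.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Trait inputs are either file paths (package TSV dialect) or
#' [summary_table] objects, or a [sim_config] whose synthetic triplet
#' stands in for all three.  All estimator settings and thresholds are
#' echoed into the run manifest for provenance.
#'
#' @param exposures Named list of exposure tables/paths (or a single one).
#' @param mediator Mediator table/path.
#' @param outcomes Named list of outcome tables/paths (or a single one).
#' @param simulation Optional [sim_config]; generates exposure/mediator/
#'   outcome synthetically (ignoring the three arguments above).
#' @param selection A [selection_config].
#' @param exclusions Optional exclusion list (path or data frame with
#'   `variant_id`, `phenotype`).
#' @param model IVW model (`"auto"`, `"fixed"`, `"random"`).
#' @param phi Mode bandwidth multiplier.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param mediation_mode `"summary"` (stage 1 from summary statistics) or
#'   `"individual"` (true 2SLS; requires `simulation`).
#' @param presso_n_sim MR-PRESSO simulations per direction (default 1000).
#' @param alpha Significance level for calls (default 0.05).
#' @param seed Global seed; every stochastic step derives its stream from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(exposures = NULL, mediator = NULL, outcomes = NULL,
                            simulation = NULL,
                            selection = selection_config(),
                            exclusions = NULL,
                            model = "auto", phi = 1, n_boot = 1000,
                            mediation_mode = c("summary", "individual"),
                            presso_n_sim = 1000, alpha = 0.05, seed = 1) {
  mediation_mode <- match.arg(mediation_mode)
  if (is.null(simulation)) {
    if (is.null(exposures) || is.null(mediator) || is.null(outcomes))
      stopf("pipeline_config needs exposures, mediator and outcomes (or a simulation config)")
    as_named_list <- function(x, default) {
      if (inherits(x, "summary_table") || is.character(x) && length(x) == 1)
        x <- stats::setNames(list(x), default)
      x
    }
    exposures <- as_named_list(exposures, "exposure")
    outcomes <- as_named_list(outcomes, "outcome")
    for (p in c(unlist(Filter(is.character, exposures)),
                unlist(Filter(is.character, outcomes)),
                if (is.character(mediator)) mediator,
                if (is.character(exclusions)) exclusions))
      if (!file.exists(p)) stopf("configured file does not exist: %s", p)
  } else {
    stopifnot(inherits(simulation, "sim_config"))
  }
  if (mediation_mode == "individual" && is.null(simulation))
    stopf("individual-level mediation requires a simulation config (cohort data)")
  structure(list(exposures = exposures, mediator = mediator,
                 outcomes = outcomes, simulation = simulation,
                 selection = selection, exclusions = exclusions,
                 model = model, phi = phi, n_boot = n_boot,
                 mediation_mode = mediation_mode,
                 presso_n_sim = presso_n_sim, alpha = alpha, seed = seed),
            class = "pipeline_config")
}

resolve_table <- function(x, trait_id, trait_type = "quantitative") {
  if (inherits(x, "summary_table")) return(x)
  read_sumstats(x, trait_id = trait_id, trait_type = trait_type)
}

# One analysis direction: select -> clump -> F filter -> exclusions ->
# harmonize -> outcome-p filter -> PRESSO removal -> Steiger -> five
# estimators.  Returns fit, sensitivity and the audit of every dropped
# instrument.
process_direction <- function(exposure, outcome, selection, exclusions,
                              model, phi, n_boot, presso_n_sim, alpha, seed) {
  cand <- select_by_pvalue(exposure, selection$p_threshold)
  cand <- clump(cand, selection$clump_r2, selection$clump_window_kb)
  cand <- filter_weak(cand, selection$f_min)
  cand <- apply_exclusions(cand, exclusions)
  kept_ids <- cand$variant_id[cand$status == "kept"]

  audit <- c(input = nrow(cand),
             subthreshold = sum(cand$drop_reason %in% "subthreshold"),
             clumped = sum(cand$drop_reason %in% "clumped"),
             weak = sum(cand$drop_reason %in% "weak"),
             confounder = sum(cand$drop_reason %in% "confounder"),
             missing_in_outcome = 0L, outcome_associated = 0L,
             presso_outlier = 0L, kept = 0L)

  fail <- function(reason) {
    audit["kept"] <- max(0L, audit["input"] - sum(audit[2:8]))
    list(failed = TRUE, fail_reason = reason, audit = audit,
         h = NULL, fit = NULL, sensitivity = NULL, steiger = NULL)
  }
  if (length(kept_ids) < 2) return(fail("fewer than 2 instruments after exposure QC"))

  h <- tryCatch(harmonize(exposure, outcome), error = function(e) NULL)
  if (is.null(h)) return(fail("no overlapping variants"))
  h <- h[h$variant_id %in% kept_ids, , drop = FALSE]
  audit["missing_in_outcome"] <- length(kept_ids) - nrow(h)

  h <- filter_outcome_associated(h, selection$outcome_p_exclude)
  audit["outcome_associated"] <- length(attr(h, "outcome_associated"))

  if (nrow(h) >= 4) {
    pres <- mr_presso(h, n_sim = presso_n_sim, seed = child_seed(seed, 11))
    h <- remove_outliers(h, pres)
    audit["presso_outlier"] <- length(attr(h, "presso_outliers"))
  } else pres <- NULL

  audit["kept"] <- nrow(h)
  if (nrow(h) < 2) return(fail("fewer than 2 instruments survive harmonization/QC"))
  if (nrow(h) < 3) return(fail("fewer than 3 instruments for the estimator panel"))

  st <- tryCatch(steiger(h), error = function(e) NULL)
  fit <- mr_fit(h, model = model, phi = phi, n_boot = n_boot,
                seed = child_seed(seed, 12), alpha = alpha)
  sens <- mr_sensitivity(h, n_sim = presso_n_sim, seed = child_seed(seed, 13))
  if (!is.null(pres)) {  # report the pre-removal global test
    sens$presso_global_pval <- pres$global_pval
    sens$n_outliers <- length(pres$outlier_ids)
  }
  list(failed = FALSE, fail_reason = NA_character_, audit = audit,
       h = h, fit = fit, sensitivity = sens, steiger = st)
}

sens_row <- function(exposure_id, outcome_id, s, failed, reason) {
  data.frame(exposure = exposure_id, outcome = outcome_id,
             failed = failed, fail_reason = reason,
             Q = s$Q %||% NA_real_, Q_df = s$Q_df %||% NA_integer_,
             Q_pval = s$Q_pval %||% NA_real_,
             egger_intercept = s$egger_intercept %||% NA_real_,
             egger_se = s$egger_se %||% NA_real_,
             egger_pval = s$egger_pval %||% NA_real_,
             presso_global_pval = s$presso_global_pval %||% NA_real_,
             n_outliers = s$n_outliers %||% NA_integer_,
             steiger_direction = s$steiger_direction %||% NA,
             steiger_pval = s$steiger_pval %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' Run the full two-step MR mediation pipeline
#'
#' Executes, per analysis direction, the instrument-selection funnel,
#' harmonization, sensitivity filters, the five-estimator panel and causal
#' call; then the stage-1 exposure-to-mediator fit, the stage-2 IVW
#' mediator-to-outcome fit, and the Sobel mediation for every
#' exposure/outcome pair.  Directions with too few surviving instruments
#' are marked failed and the pipeline continues.  All randomness derives
#' from the config seed.
#'
#' @param config A [pipeline_config].
#' @return An object of class `mr_report`: data frames `direct` (five-method
#'   rows per exposure-outcome direction), `stage1` (intercept/predicted
#'   rows per exposure), `mediator_outcome` (five-method rows per outcome),
#'   `mediation` (Sobel rows per exposure-outcome pair), `sensitivity`, and
#'   `audit` (instrument attrition per direction), plus the config echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  if (!is.null(config$simulation)) {
    trip <- make_three_gwas(config$simulation)
    exposures <- list(exposure = trip$exposure)
    mediator <- trip$mediator
    outcomes <- list(outcome = trip$outcome)
    cohort <- trip$cohort
    med_ids <- trip$subsamples$mediator
  } else {
    exposures <- lapply(stats::setNames(names(config$exposures),
                                        names(config$exposures)),
                        function(nm) resolve_table(config$exposures[[nm]], nm))
    mediator <- resolve_table(config$mediator, "mediator")
    outcomes <- lapply(stats::setNames(names(config$outcomes),
                                       names(config$outcomes)),
                       function(nm) resolve_table(config$outcomes[[nm]], nm,
                                                  trait_type = "binary"))
    cohort <- NULL
    med_ids <- NULL
  }
  exclusions <- config$exclusions
  if (is.character(exclusions)) exclusions <- read_exclusion_list(exclusions)

  direct <- stage1 <- med_out <- mediation <- sensitivity <- audit <- list()
  stage1_fits <- list()
  stage2_fits <- list()
  stream <- 0L
  next_seed <- function() { stream <<- stream + 1L; child_seed(seed, stream) }

  run_dir <- function(exp_tab, out_tab) {
    process_direction(exp_tab, out_tab, config$selection, exclusions,
                      config$model, config$phi, config$n_boot,
                      config$presso_n_sim, config$alpha, next_seed())
  }
  audit_row <- function(exposure_id, outcome_id, a)
    data.frame(exposure = exposure_id, outcome = outcome_id, t(a),
               stringsAsFactors = FALSE)

  # exposure -> outcome (direct effects)
  for (ex in names(exposures)) for (ou in names(outcomes)) {
    res <- run_dir(exposures[[ex]], outcomes[[ou]])
    audit[[length(audit) + 1L]] <- audit_row(ex, ou, res$audit)
    sensitivity[[length(sensitivity) + 1L]] <-
      sens_row(ex, ou, res$sensitivity %||% list(), res$failed, res$fail_reason)
    if (!res$failed) direct[[length(direct) + 1L]] <- mr_results_table(res$fit)
  }

  # exposure -> mediator (stage 1)
  for (ex in names(exposures)) {
    res <- run_dir(exposures[[ex]], mediator)
    audit[[length(audit) + 1L]] <- audit_row(ex, "mediator", res$audit)
    sensitivity[[length(sensitivity) + 1L]] <-
      sens_row(ex, "mediator", res$sensitivity %||% list(), res$failed,
               res$fail_reason)
    if (res$failed) next
    s1 <- if (config$mediation_mode == "individual") {
      two_stage_least_squares(
        list(genotypes = cohort$genotypes[med_ids, , drop = FALSE],
             exposure = cohort$exposure[med_ids],
             mediator = cohort$mediator[med_ids]),
        instrument_ids = res$h$variant_id)
    } else summary_stage_one(res$h)
    stage1_fits[[ex]] <- s1
    stage1[[length(stage1) + 1L]] <- data.frame(
      exposure = ex, coefficient = c("Intercept", "Predicted"),
      B = c(s1$intercept, s1$B1), S = c(s1$intercept_se, s1$S1),
      t = c(s1$intercept_t, s1$t), P = c(s1$intercept_p, s1$pval),
      R2 = c(s1$r2, NA_real_), mode = s1$mode, stringsAsFactors = FALSE)
  }

  # mediator -> outcome (stage 2) and mediation
  for (ou in names(outcomes)) {
    res <- run_dir(mediator, outcomes[[ou]])
    audit[[length(audit) + 1L]] <- audit_row("mediator", ou, res$audit)
    sensitivity[[length(sensitivity) + 1L]] <-
      sens_row("mediator", ou, res$sensitivity %||% list(), res$failed,
               res$fail_reason)
    if (res$failed) next
    med_out[[length(med_out) + 1L]] <- mr_results_table(res$fit)
    ivw_est <- res$fit$estimates[res$fit$estimates$method == "ivw", ]
    stage2_fits[[ou]] <- ivw_est
    for (ex in names(stage1_fits)) {
      s1 <- stage1_fits[[ex]]
      med <- sobel_mediation(s1$B1, s1$S1, ivw_est$b, ivw_est$se)
      mediation[[length(mediation) + 1L]] <- data.frame(
        direction = sprintf("%s -> mediator -> %s", ex, ou),
        exposure = ex, outcome = ou,
        B1 = med$b1, S1 = med$s1, B2 = med$b2, S2 = med$s2,
        Bm = med$bm, Sm = med$sm, Z = med$z, Pm = med$pval,
        ci_low = med$ci_low, ci_high = med$ci_high,
        stage2_model = ivw_est$model, stringsAsFactors = FALSE)
    }
  }

  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  structure(list(direct = bind(direct), stage1 = bind(stage1),
                 mediator_outcome = bind(med_out),
                 mediation = bind(mediation),
                 sensitivity = bind(sensitivity), audit = bind(audit),
                 config = config, seed = seed),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Two-step MR mediation report\n")
  n_dir <- if (is.null(x$audit)) 0 else nrow(x$audit)
  cat(sprintf("  %d analysis direction(s), seed %s\n", n_dir, x$seed))
  if (!is.null(x$mediation)) {
    cat("Mediation (Sobel) results:\n")
    med <- x$mediation[c("direction", "Bm", "Sm", "Z", "Pm")]
    med[-1] <- lapply(med[-1], signif, 3)
    print(med, row.names = FALSE)
  }
  invisible(x)
}

#' Write report tables and the run manifest
#'
#' Writes the report's data frames as TSV files plus a JSON manifest with
#' the configuration echo, the seed and the per-direction instrument
#' counts.  Byte-identical for identical config and seed.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("direct", "stage1", "mediator_outcome", "mediation",
            "sensitivity", "audit")
  for (nm in tabs) {
    if (is.null(report[[nm]])) next
    utils::write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- report$config
  manifest <- list(
    seed = report$seed,
    selection = unclass(cfg$selection),
    model = cfg$model, phi = cfg$phi, n_boot = cfg$n_boot,
    mediation_mode = cfg$mediation_mode, presso_n_sim = cfg$presso_n_sim,
    alpha = cfg$alpha,
    simulated = !is.null(cfg$simulation),
    counts = if (is.null(report$audit)) NULL else report$audit)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
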