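#' Bundled worked-example coefficient tables
#'
#' A published two-step analysis of lipid exposures, leukocyte telomere
#' length as the mediator, and cancer outcomes, reduced to its printed
#' coefficient tables: the stage-1 regression rows (intercept and
#' predicted slope per lipid, with B, S, t, P, R-squared) and the
#' mediation rows (Bm, Sm, Z, Pm per lipid-cancer path).  The telomere
#' length to lung cancer IVW odds ratio in that analysis was 1.411, so
#' `log(1.411)` is the stage-2 log-odds effect for the lung paths.  These
#' tables serve as worked-example inputs: feeding the stage-1 slopes and
#' the stage-2 effect through [sobel_mediation()] reproduces the mediation
#' rows.
#'
#' @return List with data frames `stage1` and `mediation`, and
#'   `or_tl_lung` (the stage-2 odds ratio for the lung paths).
#' @examples
#' ex <- worked_example_tables()
#' rc <- subset(ex$stage1, exposure == "RC" & coefficient == "Predicted")
#' sobel_mediation(rc$B, rc$S, log(ex$or_tl_lung), 0.08)$bm  # ~2.88e-2
#' @export
worked_example_tables <- function() {
  read1 <- function(f)
    utils::read.table(system.file("extdata", f, package = "mrmediate"),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  list(stage1 = read1("lipid_tl_stage1.tsv"),
       mediation = read1("lipid_tl_cancer_mediation.tsv"),
       or_tl_lung = 1.411)
}
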