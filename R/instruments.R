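#' @title Instrument selection and quality control
#' @description
#' Candidate instruments are carried as a data frame of exposure-side
#' summary records augmented with `f_stat`, `r2_exposure`, `status`
#' (`"kept"`/`"dropped"`) and `drop_reason` (one of `subthreshold`,
#' `clumped`, `weak`, `confounder`, `outcome_associated`, `presso_outlier`,
#' `missing_in_outcome`).  Every filter partitions its input: rows are never
#' discarded, only marked, so audit counts are exact.
#' @name instruments
NULL

#' Instrument-selection configuration
#'
#' Thresholds of the instrument-selection funnel: genome-wide significance
#' for the exposure association, LD-clumping parameters, the weak-instrument
#' F cutoff, and the outcome-association exclusion p-value.
#'
#' @param p_threshold Exposure p-value threshold (default `5e-8`).
#' @param clump_r2 Maximum allowed LD r-squared between retained instruments
#'   (default `0.001`).
#' @param clump_window_kb Clumping window in kilobases (default `10000`).
#' @param f_min Minimum instrument F-statistic (default `10`).
#' @param outcome_p_exclude Variants with outcome p below this are excluded
#'   (default `1e-5`).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                             clump_window_kb = 10000, f_min = 10,
                             outcome_p_exclude = 1e-5) {
  cfg <- list(p_threshold = p_threshold, clump_r2 = clump_r2,
              clump_window_kb = clump_window_kb, f_min = f_min,
              outcome_p_exclude = outcome_p_exclude)
  if (any(unlist(cfg) <= 0)) stopf("all selection thresholds must be positive")
  structure(cfg, class = "selection_config")
}

as_instruments <- function(table) {
  df <- as.data.frame(table)
  df$f_stat <- (df$beta / df$se)^2
  df$r2_exposure <- ifelse(is.na(df$n), NA_real_,
                           df$f_stat / (df$f_stat + df$n - 2))
  df$status <- "kept"
  df$drop_reason <- NA_character_
  df
}

#' Select instrument candidates by exposure p-value
#'
#' @param table A [summary_table] for the exposure.
#' @param p_threshold Significance threshold (records with `pval <
#'   p_threshold` are kept).
#' @return Instrument data frame with `status`/`drop_reason` set
#'   (`subthreshold` for the rest) and `f_stat`/`r2_exposure` computed.
#' @export
select_by_pvalue <- function(table, p_threshold = 5e-8) {
  df <- if (inherits(table, "summary_table")) as_instruments(table) else table
  drop <- df$status == "kept" & df$pval >= p_threshold
  df$status[drop] <- "dropped"
  df$drop_reason[drop] <- "subthreshold"
  df
}

#' Instrument strength: F-statistic and variance explained
#'
#' The single-SNP F approximation `F = (beta/se)^2`; with a known sample
#' size, the variance explained follows as `r2 = F / (F + n - 2)`.
#'
#' @param beta,se Effect and standard error.
#' @param n Optional sample size.
#' @return A list with `f_stat` and `r2` (`NA` without `n`).
#' @export
compute_f <- function(beta, se, n = NA) {
  if (any(se <= 0)) stopf("se must be positive")
  f <- (beta / se)^2
  list(f_stat = f, r2 = ifelse(is.na(n), NA_real_, f / (f + n - 2)))
}

#' Drop weak instruments by F-statistic
#'
#' @param candidates Instrument data frame.
#' @param f_min Minimum F (kept requires `f_stat > f_min`).
#' @return The data frame with weak instruments marked `drop_reason = "weak"`.
#' @export
filter_weak <- function(candidates, f_min = 10) {
  drop <- candidates$status == "kept" & candidates$f_stat <= f_min
  candidates$status[drop] <- "dropped"
  candidates$drop_reason[drop] <- "weak"
  candidates
}

#' Greedy LD/distance clumping of instrument candidates
#'
#' Repeatedly takes the remaining candidate with the lowest p-value and drops
#' every other candidate on the same chromosome within `clump_window_kb`
#' whose LD r-squared with it exceeds `clump_r2`.  Without an LD matrix all
#' same-window pairs are treated as exceeding the threshold (distance-only
#' thinning).  Ties in p-value are broken by `variant_id`, so the result is
#' independent of input order.
#'
#' @param candidates Instrument data frame (only `status == "kept"` rows
#'   participate).
#' @param clump_r2 r-squared threshold (default 0.001).
#' @param clump_window_kb Window in kb (default 10000).
#' @param ld Optional symmetric matrix of r-squared values with variant ids
#'   as dimnames; pairs absent from the matrix are treated as r2 = 0 with a
#'   warning.
#' @return The data frame with clumped candidates marked
#'   `drop_reason = "clumped"`.
#' @export
clump <- function(candidates, clump_r2 = 0.001, clump_window_kb = 10000, ld = NULL) {
  active <- which(candidates$status == "kept")
  if (length(active) <= 1) return(candidates)
  ord <- active[order(candidates$pval[active], candidates$variant_id[active])]
  window_bp <- clump_window_kb * 1000
  warned <- FALSE
  alive <- rep(TRUE, nrow(candidates))

  pair_r2 <- function(id_a, id_b) {
    if (is.null(ld)) return(1)  # distance-only: treat as linked
    if (!is.null(dimnames(ld)) && id_a %in% rownames(ld) && id_b %in% colnames(ld))
      return(ld[id_a, id_b])
    if (!warned) {
      warnf("LD matrix missing pair(s) (e.g. %s/%s); treating as r2 = 0", id_a, id_b)
      warned <<- TRUE
    }
    0
  }

  for (i in ord) {
    if (!alive[i] || candidates$status[i] != "kept") next
    for (j in ord) {
      if (j == i || !alive[j]) next
      same_chr <- candidates$chrom[j] == candidates$chrom[i]
      close_by <- same_chr &&
        abs(candidates$pos[j] - candidates$pos[i]) <= window_bp
      if (close_by &&
          pair_r2(candidates$variant_id[i], candidates$variant_id[j]) > clump_r2) {
        alive[j] <- FALSE
        candidates$status[j] <- "dropped"
        candidates$drop_reason[j] <- "clumped"
      }
    }
  }
  candidates
}

#' Read a variant exclusion list
#'
#' Tab-separated file with columns `variant_id` and `phenotype` (free-text
#' annotation of the confounding trait the variant is associated with).
#'
#' @param path File path.
#' @return Data frame with `variant_id`, `phenotype`.
#' @export
read_exclusion_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (!"variant_id" %in% names(df)) stopf("exclusion list needs a variant_id column")
  if (!"phenotype" %in% names(df)) df$phenotype <- ""
  df$variant_id <- as.character(df$variant_id)
  if (any(!nzchar(df$variant_id))) stopf("exclusion list has empty variant_id")
  df[c("variant_id", "phenotype")]
}

#' Exclude instruments associated with confounding phenotypes
#'
#' Candidates whose `variant_id` appears in the exclusion list are marked
#' `drop_reason = "confounder"`; the phenotype annotation is kept in the
#' `confounder_phenotype` column for the audit log.
#'
#' @param candidates Instrument data frame.
#' @param exclusions Data frame with `variant_id` (and optionally
#'   `phenotype`), e.g. from [read_exclusion_list()], or `NULL` for no-op.
#' @return The updated data frame.
#' @export
apply_exclusions <- function(candidates, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(candidates)
  idx <- match(candidates$variant_id, as.character(exclusions$variant_id))
  hit <- !is.na(idx) & candidates$status == "kept"
  candidates$status[hit] <- "dropped"
  candidates$drop_reason[hit] <- "confounder"
  if (!"confounder_phenotype" %in% names(candidates))
    candidates$confounder_phenotype <- NA_character_
  if ("phenotype" %in% names(exclusions))
    candidates$confounder_phenotype[hit] <-
      as.character(exclusions$phenotype)[idx[hit]]
  candidates
}

#' Remove variants strongly associated with the outcome
#'
#' Instruments whose outcome-side p-value falls below the exclusion
#' threshold violate the exclusion-restriction assumption and are removed
#' from the harmonized table.
#'
#' @param h A `harmonized_table`.
#' @param outcome_p_exclude Threshold (default `1e-5`).
#' @return The filtered `harmonized_table`; removed ids are recorded in the
#'   `"outcome_associated"` attribute.
#' @export
filter_outcome_associated <- function(h, outcome_p_exclude = 1e-5) {
  bad <- !is.na(h$pval_y) & h$pval_y < outcome_p_exclude
  removed <- h$variant_id[bad]
  out <- h[!bad, , drop = FALSE]
  attr(out, "outcome_associated") <- removed
  out
}
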