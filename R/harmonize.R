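#' @title Harmonized exposure/outcome effect pairs
#' @description
#' Harmonization aligns the per-variant effects of an exposure table and an
#' outcome table onto a common effect allele (the exposure's), so that every
#' downstream estimator works with pairs (beta_x, beta_y) reported for the
#' same allele.  Outcome effects reported for the opposite allele are
#' sign-flipped; palindromic variants (A/T, C/G) are resolved or dropped
#' according to the chosen policy; strand-incompatible allele sets are
#' dropped.
#' @name harmonize
NULL

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Build a harmonized table directly from aligned effect pairs
#'
#' Constructor for pre-harmonized data (or simulation output): all effects
#' are assumed to refer to a common effect allele already.
#'
#' @param df Data frame with at least `beta_x`, `se_x`, `beta_y`, `se_y`;
#'   optional `variant_id`, `pval_x`, `pval_y`, `eaf_x`, `n_x`, `n_y`,
#'   `palindromic`, `flipped`.
#' @param exposure_id,outcome_id Trait labels.
#' @return A `harmonized_table` (a `data.frame` subclass).
#' @export
harmonized_table <- function(df, exposure_id = "exposure", outcome_id = "outcome") {
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% names(df)))
    stopf("harmonized_table needs columns %s", paste(need, collapse = ", "))
  if (!"variant_id" %in% names(df))
    df$variant_id <- sprintf("snp%04d", seq_len(nrow(df)))
  if (anyDuplicated(df$variant_id)) stopf("duplicate variant_id in harmonized table")
  if (any(df$se_x <= 0) || any(df$se_y <= 0)) stopf("all standard errors must be positive")
  for (col in c("pval_x", "pval_y", "eaf_x", "eaf_y", "n_x", "n_y"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"palindromic" %in% names(df)) df$palindromic <- FALSE
  if (!"flipped" %in% names(df)) df$flipped <- FALSE
  rownames(df) <- NULL
  structure(df, exposure_id = exposure_id, outcome_id = outcome_id,
            class = c("harmonized_table", "data.frame"))
}

#' Harmonize exposure and outcome summary tables onto a common effect allele
#'
#' Variants present in both tables are aligned so that the outcome effect
#' refers to the exposure's effect allele.  When the outcome's effect allele
#' equals the exposure's other allele, the outcome beta is negated and its
#' frequency complemented (`flipped = TRUE`).  Alleles reported on the
#' opposite strand are complemented before matching; allele sets that match
#' in no orientation are dropped.  Palindromic variants (A/T or C/G) cannot
#' be resolved by allele letters: under `palindrome_policy = "drop"` they are
#' removed, under `"infer_by_eaf"` the orientation is inferred by comparing
#' the two frequencies to 0.5, dropping variants whose frequency on either
#' side falls inside the ambiguous band `0.5 +/- eaf_tolerance`.
#'
#' @param exposure,outcome [summary_table] objects.
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eaf_tolerance Half-width of the ambiguous frequency band around 0.5
#'   (default 0.08, i.e. drop palindromes with eaf in (0.42, 0.58)).
#' @return A `harmonized_table` with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, exposure-side `eaf_x`, `beta_x`,
#'   `se_x`, `pval_x`, `n_x`, outcome-side `eaf_y`, `beta_y`, `se_y`,
#'   `pval_y`, `n_y`, and flags `palindromic`, `flipped`.  Attribute
#'   `"drops"` counts variants removed per reason.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop"),
                      eaf_tolerance = 0.08) {
  stopifnot(inherits(exposure, "summary_table"), inherits(outcome, "summary_table"))
  palindrome_policy <- match.arg(palindrome_policy)
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)
  shared <- intersect(ex$variant_id, ou$variant_id)
  drops <- c(missing_in_outcome = nrow(ex) - length(shared),
             incompatible_alleles = 0L, palindromic = 0L, ambiguous_eaf = 0L)
  if (length(shared) == 0)
    stopf("no overlapping variants between '%s' and '%s'",
          attr(exposure, "trait_id"), attr(outcome, "trait_id"))
  ex <- ex[match(shared, ex$variant_id), ]
  ou <- ou[match(shared, ou$variant_id), ]

  n <- length(shared)
  keep <- rep(TRUE, n)
  flipped <- rep(FALSE, n)
  palin <- rep(FALSE, n)
  beta_y <- ou$beta
  eaf_y <- ou$eaf

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    is_palin <- COMPLEMENT[[ea_x]] == oa_x
    palin[i] <- is_palin

    if (!is_palin) {
      same <- (ea_y == ea_x && oa_y == oa_x) ||
        (COMPLEMENT[[ea_y]] == ea_x && COMPLEMENT[[oa_y]] == oa_x)
      swapped <- (ea_y == oa_x && oa_y == ea_x) ||
        (COMPLEMENT[[ea_y]] == oa_x && COMPLEMENT[[oa_y]] == ea_x)
      if (same) {
        flipped[i] <- FALSE
      } else if (swapped) {
        flipped[i] <- TRUE
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- if (is.na(eaf_y[i])) NA_real_ else 1 - eaf_y[i]
      } else {
        keep[i] <- FALSE
        drops["incompatible_alleles"] <- drops["incompatible_alleles"] + 1L
      }
      next
    }

    # palindromic: letters cannot resolve the strand
    letters_ok <- (ea_y == ea_x && oa_y == oa_x) || (ea_y == oa_x && oa_y == ea_x)
    if (!letters_ok) {
      keep[i] <- FALSE
      drops["incompatible_alleles"] <- drops["incompatible_alleles"] + 1L
      next
    }
    if (palindrome_policy == "drop") {
      keep[i] <- FALSE
      drops["palindromic"] <- drops["palindromic"] + 1L
      next
    }
    fx <- ex$eaf[i]
    fy <- if (ea_y == ea_x) ou$eaf[i] else 1 - ou$eaf[i]
    ambiguous <- is.na(fx) || is.na(fy) ||
      abs(fx - 0.5) < eaf_tolerance || abs(fy - 0.5) < eaf_tolerance
    if (ambiguous) {
      keep[i] <- FALSE
      drops["ambiguous_eaf"] <- drops["ambiguous_eaf"] + 1L
      next
    }
    letters_swapped <- ea_y == oa_x
    same_side <- (fx - 0.5) * (fy - 0.5) > 0
    # same side: letters told the truth; opposite side: strand flip implies
    # an additional allele swap
    flipped[i] <- if (same_side) letters_swapped else !letters_swapped
    if (flipped[i]) beta_y[i] <- -ou$beta[i] else beta_y[i] <- ou$beta[i]
    eaf_y[i] <- if (same_side) fy else 1 - fy
  }

  out <- data.frame(
    variant_id = ex$variant_id, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    eaf_x = ex$eaf, beta_x = ex$beta, se_x = ex$se, pval_x = ex$pval, n_x = ex$n,
    eaf_y = eaf_y, beta_y = beta_y, se_y = ou$se, pval_y = ou$pval, n_y = ou$n,
    palindromic = palin, flipped = flipped,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            exposure_id = attr(exposure, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            outcome_type = attr(outcome, "trait_type"),
            drops = drops,
            class = c("harmonized_table", "data.frame"))
}

#' @export
print.harmonized_table <- function(x, ...) {
  cat(sprintf("Harmonized table: %s -> %s, %d variant(s)\n",
              attr(x, "exposure_id") %||% "exposure",
              attr(x, "outcome_id") %||% "outcome", nrow(x)))
  drops <- attr(x, "drops")
  if (!is.null(drops) && sum(drops) > 0)
    cat("  removed:",
        paste(sprintf("%s=%d", names(drops)[drops > 0], drops[drops > 0]),
              collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more row(s)\n")
  invisible(x)
}

# Subsetting keeps the class and direction labels.
#' @export
`[.harmonized_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("beta_x", "beta_y") %in% names(out))) {
    attr(out, "exposure_id") <- attr(x, "exposure_id")
    attr(out, "outcome_id") <- attr(x, "outcome_id")
    attr(out, "outcome_type") <- attr(x, "outcome_type")
    class(out) <- c("harmonized_table", "data.frame")
  }
  out
}
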