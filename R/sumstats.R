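#' @title GWAS summary-statistic tables
#' @description
#' A summary table is a validated `data.frame` of per-variant association
#' records for one trait with the standard columns `variant_id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' `eaf` and `n` may be missing (`NA`); everything else is mandatory.
#' Validation drops rows that violate the record invariants (non-ACGT or
#' equal alleles, `se <= 0`, `pval` outside (0, 1], `eaf` outside (0, 1),
#' duplicated variant ids) and records the drop counts in the
#' `"drops"` attribute.
#' @name summary_table
NULL

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pval", "n")

#' Construct a validated summary table from a data frame
#'
#' @param df Data frame holding (at least) the standard columns.
#' @param trait_id Character label for the trait.
#' @param trait_type `"quantitative"` or `"binary"` (betas on the log-odds
#'   scale for binary traits).
#' @return An object of class `summary_table` (a `data.frame`) with
#'   attributes `trait_id`, `trait_type` and `drops` (named integer vector of
#'   rows removed per reason).
#' @export
summary_table <- function(df, trait_id, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(setdiff(SUMSTATS_COLS, c("eaf", "n")), names(df))
  if (length(missing_cols) > 0)
    stopf("summary table is missing mandatory column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stopf("summary table for '%s' is empty", trait_id)
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  df <- df[SUMSTATS_COLS]

  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    df[[col]] <- as.numeric(df[[col]])

  drops <- c(not_snp = 0L, same_alleles = 0L, bad_se = 0L, bad_pval = 0L,
             bad_eaf = 0L, missing_value = 0L, duplicate_id = 0L)
  bases <- c("A", "C", "G", "T")
  keep <- rep(TRUE, nrow(df))

  flag <- function(bad, reason) {
    bad <- bad & keep
    drops[reason] <<- drops[reason] + sum(bad)
    keep <<- keep & !bad
  }
  flag(is.na(df$variant_id) | is.na(df$beta) | is.na(df$se) | is.na(df$pval),
       "missing_value")
  flag(!(df$effect_allele %in% bases) | !(df$other_allele %in% bases), "not_snp")
  flag(df$effect_allele == df$other_allele, "same_alleles")
  flag(df$se <= 0, "bad_se")
  flag(df$pval <= 0 | df$pval > 1, "bad_pval")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "bad_eaf")
  flag(duplicated(df$variant_id) & keep, "duplicate_id")

  if (any(!keep))
    message(sprintf("summary_table('%s'): dropped %d of %d row(s) failing validation",
                    trait_id, sum(!keep), nrow(df)))
  out <- df[keep, , drop = FALSE]
  if (nrow(out) == 0) stopf("no valid records remain for trait '%s'", trait_id)
  rownames(out) <- NULL
  structure(out,
            trait_id = trait_id, trait_type = trait_type, drops = drops,
            class = c("summary_table", "data.frame"))
}

#' Read a GWAS summary-statistic table from delimited text
#'
#' Reads a tab-separated (or otherwise delimited) file with a header row,
#' renames columns through `column_map`, and validates every row into a
#' [summary_table].  Rows failing the record invariants are dropped with a
#' logged count.
#'
#' @param path Path to the file.
#' @param trait_id Trait label stored on the table.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param column_map Optional named character vector mapping standard column
#'   names to the file's header names, e.g.
#'   `c(variant_id = "SNP", pval = "p")`.  Unmapped standard names are looked
#'   up verbatim.
#' @param sep Field separator (default tab).
#' @return A [summary_table].
#' @export
read_sumstats <- function(path, trait_id, trait_type = c("quantitative", "binary"),
                          column_map = NULL, sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stopf("summary-statistic file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  if (nrow(df) == 0) stopf("summary-statistic file is empty: %s", path)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df))
        stopf("mapped column '%s' (for '%s') not found in %s", src, std, path)
      names(df)[names(df) == src] <- std
    }
  }
  mandatory <- setdiff(SUMSTATS_COLS, c("eaf", "n"))
  absent <- setdiff(mandatory, names(df))
  if (length(absent) > 0)
    stopf("missing mandatory column(s) in %s: %s", path,
          paste(absent, collapse = ", "))
  summary_table(df, trait_id = trait_id, trait_type = trait_type)
}

#' Write a summary table as tab-separated text
#'
#' Writes the standard ten columns with a header row; `NA` is written for
#' missing `eaf`/`n`.  A table written and re-read round-trips unchanged.
#'
#' @param x A [summary_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "summary_table"))
  utils::write.table(as.data.frame(x)[SUMSTATS_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fill missing effect-allele frequencies from a reference
#'
#' Records with missing `eaf` receive the reference frequency matched on
#' `variant_id`: the value itself when the reference is keyed to the same
#' effect allele, its complement `1 - eaf` when keyed to the record's other
#' allele.  Records with no usable match keep a missing `eaf` and are flagged
#' in the `"eaf_unmatched"` attribute.
#'
#' @param table A [summary_table].
#' @param reference Data frame with columns `variant_id`, `effect_allele`,
#'   `eaf` (frequencies in (0, 1)).
#' @return The completed [summary_table].
#' @export
fill_missing_eaf <- function(table, reference) {
  stopifnot(inherits(table, "summary_table"))
  need <- c("variant_id", "effect_allele", "eaf")
  if (!all(need %in% names(reference)))
    stopf("reference must have columns %s", paste(need, collapse = ", "))
  if (any(reference$eaf <= 0 | reference$eaf >= 1, na.rm = TRUE))
    stopf("reference eaf values must lie in (0, 1)")
  ref_allele <- toupper(as.character(reference$effect_allele))
  idx <- match(table$variant_id, as.character(reference$variant_id))
  missing_eaf <- is.na(table$eaf)
  unmatched <- character(0)
  for (i in which(missing_eaf)) {
    j <- idx[i]
    if (is.na(j)) { unmatched <- c(unmatched, table$variant_id[i]); next }
    if (ref_allele[j] == table$effect_allele[i]) {
      table$eaf[i] <- reference$eaf[j]
    } else if (ref_allele[j] == table$other_allele[i]) {
      table$eaf[i] <- 1 - reference$eaf[j]
    } else {
      unmatched <- c(unmatched, table$variant_id[i])
    }
  }
  attr(table, "eaf_unmatched") <- unmatched
  table
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("GWAS summary table: %s (%s), %d variant(s)\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  drops <- attr(x, "drops")
  if (!is.null(drops) && sum(drops) > 0)
    cat("  dropped on ingest:",
        paste(sprintf("%s=%d", names(drops)[drops > 0], drops[drops > 0]),
              collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more row(s)\n")
  invisible(x)
}
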