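#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` with the global random-number generator seeded at `seed`, then
#' restores whatever RNG state was in place before the call.  Used internally
#' so that bootstrap and simulation routines are reproducible without
#' clobbering the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream unchanged.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream label, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + as.integer(stream) * 12347L) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided normal p-value for an estimate/SE pair.
z_pval <- function(b, se) 2 * stats::pnorm(-abs(b / se))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
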