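# Small programmatic fixtures shared across test files.

# A well-formed summary-statistics data frame; override any column.
make_sumstats_df <- function(n = 5, ...) {
  df <- data.frame(
    variant_id = sprintf("rs%03d", seq_len(n)),
    chrom = rep("1", n),
    pos = seq_len(n) * 1000L,
    effect_allele = rep(c("A", "C", "G", "T", "A"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C", "C"), length.out = n),
    eaf = seq(0.1, 0.45, length.out = n),
    beta = seq(-0.2, 0.2, length.out = n),
    se = rep(0.05, n),
    pval = seq(1e-12, 0.5, length.out = n),
    n = rep(10000, n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

make_table <- function(n = 5, trait_id = "trait", trait_type = "quantitative", ...) {
  summary_table(make_sumstats_df(n, ...), trait_id = trait_id,
                trait_type = trait_type)
}

# Harmonized table straight from effect pairs.
make_h <- function(beta_x, beta_y, se_x = 0.01, se_y = 0.02, ...) {
  k <- length(beta_x)
  harmonized_table(data.frame(beta_x = beta_x, beta_y = beta_y,
                              se_x = rep_len(se_x, k), se_y = rep_len(se_y, k),
                              ...))
}

# Random harmonized table under a fixed seed (proportional effects + noise).
random_h <- function(k = 10, slope = 0.4, seed = 1, het = 0) {
  set.seed(seed)
  beta_x <- rnorm(k, 0, 0.1)
  se_y <- runif(k, 0.01, 0.05)
  beta_y <- slope * beta_x + rnorm(k, 0, sqrt(het^2 + se_y^2))
  make_h(beta_x, beta_y, se_x = 0.005, se_y = se_y)
}

# Independent weighted-median oracle: direct recomputation of the
# cumulative-weight crossing (midpoint convention).
oracle_weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(b[1])
  if (p[length(p)] <= 0.5) return(b[length(b)])
  stats::approx(p, b, xout = 0.5)$y
}
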