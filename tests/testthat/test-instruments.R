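test_that("p-value selection matches a brute-force filter and partitions input", {
  tab <- make_table(2, pval = c(1e-9, 1e-7))
  cand <- select_by_pvalue(tab, 5e-8)
  expect_equal(cand$status, c("kept", "dropped"))
  expect_equal(cand$drop_reason, c(NA, "subthreshold"))

  cand <- select_by_pvalue(make_table(3, pval = rep(1, 3)), 5e-8)
  expect_equal(sum(cand$status == "kept"), 0)

  set.seed(11)
  tab <- make_table(100, pval = 10^runif(100, -12, 0))
  cand <- select_by_pvalue(tab, 5e-8)
  expect_setequal(cand$variant_id[cand$status == "kept"],
                  tab$variant_id[tab$pval < 5e-8])
  # kept + dropped partitions the input with exactly one reason each
  expect_equal(nrow(cand), 100)
  expect_true(all(is.na(cand$drop_reason) == (cand$status == "kept")))
})

test_that("selection is monotone in the threshold", {
  set.seed(12)
  tab <- make_table(50, pval = 10^runif(50, -10, 0))
  kept <- function(thr) {
    cand <- select_by_pvalue(tab, thr)
    cand$variant_id[cand$status == "kept"]
  }
  thresholds <- 10^seq(-9, -2, by = 1)
  for (i in seq_along(thresholds)[-1])
    expect_true(all(kept(thresholds[i - 1]) %in% kept(thresholds[i])))
})

test_that("distance-only clumping keeps the lowest-p variant per window", {
  tab <- make_table(2, chrom = c("1", "1"), pos = c(1e6, 6e6),
                    pval = c(1e-10, 1e-9))
  cand <- clump(select_by_pvalue(tab, 1))
  expect_equal(cand$status, c("kept", "dropped"))
  expect_equal(cand$drop_reason[2], "clumped")

  # different chromosomes: both kept
  tab <- make_table(2, chrom = c("1", "2"), pos = c(1e6, 2e6),
                    pval = c(1e-10, 1e-9))
  cand <- clump(select_by_pvalue(tab, 1))
  expect_equal(cand$status, c("kept", "kept"))

  # beyond the window on the same chromosome: both kept
  tab <- make_table(2, chrom = c("1", "1"), pos = c(1e6, 2e7),
                    pval = c(1e-10, 1e-9))
  expect_equal(clump(select_by_pvalue(tab, 1))$status, c("kept", "kept"))
})

test_that("LD-matrix clumping equals a brute-force greedy oracle and ignores order", {
  set.seed(13)
  n <- 20
  tab <- make_table(n, chrom = rep("1", n), pos = sort(sample.int(5e7, n)),
                    pval = 10^runif(n, -15, -8))
  ids <- tab$variant_id
  ld <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    ld[i, j] <- ld[j, i] <- sample(c(0, 0.001, 0.5), 1, prob = c(0.6, 0.2, 0.2))
  diag(ld) <- 1

  # independent greedy oracle over the candidate order
  oracle <- function(tab, ld, r2 = 0.001, window = 1e7) {
    left <- tab[order(tab$pval, tab$variant_id), ]
    kept <- character(0)
    while (nrow(left) > 0) {
      top <- left[1, ]
      kept <- c(kept, top$variant_id)
      near <- left$chrom == top$chrom & abs(left$pos - top$pos) <= window &
        left$variant_id != top$variant_id &
        ld[top$variant_id, left$variant_id] > r2
      left <- left[!near & left$variant_id != top$variant_id, ]
    }
    kept
  }
  cand <- clump(select_by_pvalue(tab, 1), clump_r2 = 0.001,
                clump_window_kb = 1e4, ld = ld)
  expect_setequal(cand$variant_id[cand$status == "kept"], oracle(tab, ld))

  # permuting the input rows does not change the kept set
  perm <- sample(n)
  cand2 <- clump(select_by_pvalue(tab[perm, ], 1), clump_r2 = 0.001,
                 clump_window_kb = 1e4, ld = ld)
  expect_setequal(cand2$variant_id[cand2$status == "kept"],
                  cand$variant_id[cand$status == "kept"])

  # a pair missing from the LD matrix is treated as unlinked, with a warning
  ld_small <- ld[-1, -1]
  expect_warning(clump(select_by_pvalue(tab, 1), ld = ld_small), "r2 = 0")
})

test_that("F-statistic and variance explained follow the closed forms", {
  expect_equal(compute_f(0.3, 0.03)$f_stat, 100)
  expect_equal(compute_f(0.1, 0.05)$f_stat, 4)
  expect_equal(compute_f(0.3, 0.03, n = 1000)$r2, 100 / 1098)
  expect_error(compute_f(0.1, 0), "positive")

  cand <- select_by_pvalue(make_table(2, beta = c(0.3, 0.1), se = c(0.03, 0.05),
                                      pval = c(1e-10, 1e-10)), 1)
  cand <- filter_weak(cand, f_min = 10)
  expect_equal(cand$status, c("kept", "dropped"))
  expect_equal(cand$drop_reason[2], "weak")
})

test_that("confounder exclusions equal the set difference and keep annotations", {
  cand <- select_by_pvalue(make_table(3, pval = rep(1e-10, 3)), 1)
  expect_equal(apply_exclusions(cand, NULL)$status, rep("kept", 3))

  excl <- data.frame(variant_id = "rs002", phenotype = "smoking")
  out <- apply_exclusions(cand, excl)
  expect_equal(sum(out$status == "kept"), 2)
  expect_equal(out$confounder_phenotype[out$variant_id == "rs002"], "smoking")

  set.seed(14)
  for (rep in 1:10) {
    cand <- select_by_pvalue(make_table(20, pval = rep(1e-10, 20)), 1)
    listed <- sample(cand$variant_id, sample(0:20, 1))
    out <- apply_exclusions(cand, data.frame(variant_id = listed))
    expect_setequal(out$variant_id[out$status == "kept"],
                    setdiff(cand$variant_id, listed))
  }
})

test_that("outcome-associated instruments are excluded at the configured p", {
  h <- make_h(beta_x = c(0.1, 0.1, 0.1), beta_y = c(0.05, 0.05, 0.05),
              pval_y = c(1e-6, 1e-4, 0.5))
  out <- filter_outcome_associated(h, 1e-5)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "outcome_associated"), "snp0001")

  set.seed(15)
  pv <- runif(50)^4
  h <- make_h(rep(0.1, 50), rep(0.05, 50), pval_y = pv)
  out <- filter_outcome_associated(h, 0.01)
  expect_setequal(out$variant_id, h$variant_id[pv >= 0.01])
})
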