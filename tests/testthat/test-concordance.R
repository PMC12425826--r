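test_that("call taxonomy reproduces hand-computed counts and rates", {
  # truth = test with full coverage: all TP, error rates zero
  truth <- list(snps = c(10L, 20L, 30L), aligned = rep(TRUE, 100L))
  test <- list(calls = data.frame(pos = c(10L, 20L, 30L), het = FALSE),
               covered = rep(TRUE, 100L))
  tx <- classify_calls(truth, test)
  expect_equal(tx$TP, 3L)
  expect_equal(tx$FDR, 0)
  expect_equal(tx$FNR, 0)

  # 8 TP, 2 FP, 2 covered truth missing: FDR = FNR = 0.2
  truth2 <- list(snps = 1:10 * 10L, aligned = rep(TRUE, 200L))
  test2 <- list(calls = data.frame(pos = c(1:8 * 10L, 101L, 102L), het = FALSE),
                covered = rep(TRUE, 200L))
  tx2 <- classify_calls(truth2, test2)
  expect_equal(tx2$TP, 8L)
  expect_equal(tx2$FN, 2L)
  expect_equal(tx2$FP_non_snp, 2L)
  expect_equal(tx2$FDR, 0.2)
  expect_equal(tx2$FNR, 0.2)

  # empty test set: FNR 1 over covered truth, FDR is NA (never 0)
  tx3 <- classify_calls(truth2, list(calls = data.frame(pos = integer(0),
                                                        het = logical(0)),
                                     covered = rep(TRUE, 200L)))
  expect_equal(tx3$FNR, 1)
  expect_true(is.na(tx3$FDR))

  # uncovered truth sites are "uncalled", not FN; unaligned FPs separated;
  # het call at a truth site stays FP_het
  covered <- rep(TRUE, 200L); covered[10L] <- FALSE
  aligned <- rep(TRUE, 200L); aligned[150L] <- FALSE
  tx4 <- classify_calls(list(snps = c(10L, 20L, 30L), aligned = aligned),
                        list(calls = data.frame(pos = c(20L, 30L, 150L, 160L),
                                                het = c(FALSE, TRUE, FALSE, FALSE)),
                             covered = covered))
  expect_equal(tx4$uncalled, 1L)
  expect_equal(tx4$FP_het, 1L)
  expect_equal(tx4$FP_unaligned, 1L)
  expect_equal(tx4$FP_non_snp, 1L)
  expect_equal(tx4$TP + tx4$FN + tx4$uncalled, 3L)
})

test_that("recovered FDR/FNR stay inside exact binomial intervals", {
  set.seed(70)
  n_truth <- 2000L
  fdr <- 0.07; fnr <- 0.20
  for (rep in 1:5) {
    truth_pos <- sort(sample.int(100000L, n_truth))
    cs <- simulate_call_set(truth_pos, 100000L, fdr_target = fdr,
                            fnr_target = fnr, uncovered_fraction = 0.05,
                            het_count = 5L, seed = 70L + rep)
    tx <- classify_calls(list(snps = truth_pos, aligned = rep(TRUE, 100000L)),
                         cs)
    n_cov <- tx$TP + tx$FN
    fn_lo <- qbinom(0.005, n_cov, fnr); fn_hi <- qbinom(0.995, n_cov, fnr)
    expect_true(tx$FN >= fn_lo && tx$FN <= fn_hi)
    n_calls <- tx$n_calls
    fp <- tx$FP_non_snp + tx$FP_unaligned + tx$FP_het
    fp_lo <- qbinom(0.005, n_calls, fdr); fp_hi <- qbinom(0.995, n_calls, fdr)
    expect_true(fp >= fp_lo && fp <= fp_hi)
    expect_equal(tx$TP + tx$FN + tx$uncalled, n_truth)
  }
})

test_that("error rates are reported per truth/reference pairing", {
  set.seed(72)
  truth_pos <- sort(sample.int(50000L, 800L))
  # two reference choices with different coverage masks and call sets
  tx <- lapply(c(3L, 4L), function(k) {
    cs <- simulate_call_set(truth_pos, 50000L, fdr_target = 0.02 * k,
                            fnr_target = 0.05 * k, uncovered_fraction = 0.02 * k,
                            seed = 100L + k)
    classify_calls(list(snps = truth_pos, aligned = rep(TRUE, 50000L)), cs)
  })
  expect_false(isTRUE(all.equal(tx[[1L]]$FDR, tx[[2L]]$FDR)))
  expect_false(isTRUE(all.equal(tx[[1L]]$FNR, tx[[2L]]$FNR)))
  expect_gt(tx[[2L]]$FNR, tx[[1L]]$FNR)
})

test_that("expression concordance applies the 30% / six-count rules", {
  expect_equal(expression_concordance(10, 5), "discordant")    # 0.5 <= 0.7
  expect_equal(expression_concordance(10, 9), "concordant")    # 0.9
  expect_equal(expression_concordance(5, 3), "excluded")       # max < 6
  expect_equal(expression_concordance(c(10, 10, 5), c(5, 9, 3)),
               c("discordant", "concordant", "excluded"))
  expect_equal(expression_concordance(6, 0), "discordant")     # 0/6 = 0
  expect_error(expression_concordance(-1, 5), "non-negative")
})

test_that("methylation level and concordance follow the ratio rules", {
  expect_equal(methylation_level(8, 2), 0.8)
  expect_equal(methylation_level(5, 0), 1.0)
  expect_true(is.na(methylation_level(0, 0)))
  expect_error(methylation_level(-1, 2), "non-negative")

  expect_equal(methylation_concordance(0.8, 0.3), "discordant") # 0.375 <= 0.5
  expect_equal(methylation_concordance(0.5, 0.5), "concordant")
  expect_equal(methylation_concordance(0.0, 0.0), "concordant") # equal-zero policy
  expect_equal(methylation_concordance(NA, 0.5), "excluded")
  expect_equal(methylation_concordance(0.8, 0.5), "concordant") # 0.625 > 0.5
})

test_that("quantile normalization pins q20 to 0 and q80 to 1", {
  x <- 0:100
  z <- quantile_normalize(x)
  expect_equal(unname(quantile(z, 0.2)), 0)
  expect_equal(unname(quantile(z, 0.8)), 1)
  # affine invariance
  z2 <- quantile_normalize(5 * x + 11)
  expect_equal(z2, z)
  set.seed(71)
  y <- rnorm(500)
  expect_equal(quantile_normalize(3.2 * y - 7), quantile_normalize(y))
  expect_error(quantile_normalize(rep(4, 10)), "distinct")
})
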