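test_that("exact-test mass matches hand-evaluated values", {
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5)
  expect_equal(ac_probability(1, 1, 1e6, 1e6), 0.25)
  expect_equal(ac_probability(2, 0, 1e6, 1e6), 0.125)
  expect_error(ac_probability(-1, 0, 10, 10), "non-negative")
})

test_that("log-gamma mass agrees with direct arithmetic for x, y <= 30", {
  for (Ns in list(c(1e6, 1e6), c(5473192, 5763743), c(1000, 3000))) {
    for (x in 0:30) {
      y <- 0:30
      got <- ac_probability(x, y, Ns[1], Ns[2])
      want <- ac_prob_direct(x, y, Ns[1], Ns[2])
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("the mass is symmetric in x and y when N1 = N2", {
  for (x in c(0, 1, 5, 20)) for (y in c(0, 2, 7, 30)) {
    expect_equal(ac_probability(x, y, 3e6, 3e6),
                 ac_probability(y, x, 3e6, 3e6))
  }
})

test_that("the mass normalizes: partial sums rise to 1 and never exceed it", {
  for (Ns in list(c(1e6, 1e6), c(2e6, 5e6), c(777777, 333333))) {
    for (x in c(0, 3, 17, 50)) {
      sums <- cumsum(ac_probability(x, 0:4000, Ns[1], Ns[2]))
      expect_true(all(sums <= 1 + 1e-9))
      expect_equal(sums[length(sums)], 1, tolerance = 1e-9)
    }
  }
})

test_that("the mass equals the equivalent negative-binomial density", {
  # independent closed-form check: p(y|x) is NB(size = x + 1, prob = N1/(N1+N2))
  x <- c(0, 2, 9, 40); y <- c(5, 0, 9, 123)
  N1 <- 5473192; N2 <- 5763743
  expect_equal(ac_probability(x, y, N1, N2),
               dnbinom(y, size = x + 1, prob = N1 / (N1 + N2)),
               tolerance = 1e-12)
})

test_that("two-sided p-values match brute-force tail summation", {
  expect_equal(ac_pvalue(5, 5, 1e6, 1e6), 1)
  expect_lt(ac_pvalue(50, 0, 1e6, 1e6), 1e-9)
  expect_equal(ac_pvalue(50, 0, 1e6, 1e6), 2 * 2^-51, tolerance = 1e-10)
  cases <- expand.grid(x = c(0, 1, 7, 30), y = c(0, 3, 12, 60))
  for (Ns in list(c(1e6, 1e6), c(1e6, 2.5e6))) {
    got <- ac_pvalue(cases$x, cases$y, Ns[1], Ns[2])
    want <- mapply(ac_pvalue_brute, cases$x, cases$y, Ns[1], Ns[2])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the hand-worked step-up example", {
  expect_equal(fdr_adjust(c(0.001, 0.01, 0.02, 0.03)),
               c(0.004, 0.02, 0.08 / 3, 0.03))
  expect_equal(fdr_adjust(rep(0.5, 6)), rep(0.5, 6))
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("q-values are monotone in p and BY is more conservative", {
  set.seed(7)
  p <- runif(500)
  q <- fdr_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p))
  expect_true(all(fdr_adjust(p, "BY") >= q))
})

test_that("DTG calling respects inclusive boundaries and the gray class", {
  th <- calling_thresholds()
  expect_equal(call_dtg(0.0005, 1.0, FALSE, th), "up")
  expect_equal(call_dtg(0.001, -2, FALSE, th), "down")
  expect_equal(call_dtg(0.01, 3, FALSE, th), "not_significant")
  expect_equal(call_dtg(0.0005, 0.5, FALSE, th), "not_significant")
  expect_equal(call_dtg(1e-9, NA, TRUE, th), "undetected")
  expect_error(calling_thresholds(fdr_max = 0), "\\(0, 1\\]")
})

test_that("identical libraries as both arms yield no calls", {
  sim <- gen_counts(count_sim_spec(n_genes = 200, baseline_mean = 80, seed = 21))
  lib <- sim$libraries[["PR"]]
  res <- run_comparison(lib, lib)
  expect_equal(res$p_value[!is.na(res$log2_ratio)],
               rep(1, sum(!is.na(res$log2_ratio))), tolerance = 1e-9)
  expect_true(all(res$call %in% c("not_significant", "undetected")))
})

test_that("run_comparison computes records consistently", {
  pair <- make_library_pair(x = c(0, 10, 100, 3), y = c(5, 10, 400, 0))
  res <- run_comparison(pair$control, pair$treatment)
  expect_equal(res$N1, rep(113, 4))
  expect_equal(res$N2, rep(415, 4))
  # undetected where either library has zero expression
  expect_equal(res$call[c(1, 4)], c("undetected", "undetected"))
  # log2 ratio from RPKM, not raw counts
  expect_equal(res$log2_ratio[3],
               log2((400 / 415) / (100 / 113)))
  expect_equal(res$p_value, ac_pvalue(res$x, res$y, 113, 415))
  expect_equal(res$q_value, fdr_adjust(res$p_value))
  other <- make_library_pair(c(1, 2), c(3, 4))
  expect_error(run_comparison(pair$control, other$treatment), "gene list")
})

test_that("planted fold changes are recovered with the right direction", {
  planted <- data.frame(gene = 1:6, comparison = "CR",
                        log2fc = rep(c(3, -3), 3))
  hits <- 0L
  for (s in 1:10) {
    sim <- gen_counts(count_sim_spec(n_genes = 150, baseline_mean = 1000,
                                     dispersion = 0, planted_de = planted,
                                     seed = s))
    res <- run_comparison(sim$libraries[["CR"]], sim$libraries[["CR-salt"]])
    calls <- res$call[match(sim$truth$gene_id, res$gene_id)]
    hits <- hits + sum(calls == ifelse(planted$log2fc > 0, "up", "down"))
  }
  expect_gte(hits / 60, 0.95)
})
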