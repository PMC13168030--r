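test_that("ratio normalization divides by the target and preserves order", {
  expect_equal(normalize_ratios(0.15, 0.15), 1.0)
  expect_equal(normalize_ratios(0, 0.15), 0)
  expect_equal(normalize_ratios(0.23, 0.20), 1.15)
  expect_equal(normalize_ratios(c(0.1, 0.3), 0.2), c(0.5, 1.5))
  expect_error(normalize_ratios(0.2, 0), "positive")
  expect_error(normalize_ratios(-0.1, 0.2), ">= 0")
})

test_that("interval binning respects the closed/open boundary rules", {
  expect_equal(unname(bin_ratios(c(1, 1, 1))), c(0, 3, 0, 0, 0))
  expect_equal(unname(bin_ratios(c(0.4, 0.5, 0.51, 1.5, 1.6, 2.5, 3.5, 3.6))),
               c(2, 2, 2, 1, 1))
  expect_equal(unname(bin_ratios(numeric(0))), rep(0L, 5))
  expect_error(bin_ratios(-0.1), ">= 0")
  expect_equal(sum(bin_ratios(runif(57, 0, 6))), 57)
})

test_that("binning agrees with the brute-force classifier", {
  set.seed(19)
  for (i in 1:100) {
    r <- c(runif(sample(1:40, 1), 0, 5), sample(c(0.5, 1.5, 2.5, 3.5),
                                                sample(0:4, 1)))
    expect_identical(bin_ratios(r), brute_bins(r))
  }
})

test_that("seeding counts follow the interval weighting and conserve N'", {
  c1 <- derive_counts(c(n1p = 0, n2p = 10, n3p = 0, n4p = 0, n5p = 0))
  expect_equal(c1, list(n2 = 0L, n1 = 10L, n0 = 0L, Np = 10L))
  c2 <- derive_counts(c(n1p = 1, n2p = 8, n3p = 1, n4p = 0, n5p = 0))
  expect_equal(c2, list(n2 = 1L, n1 = 8L, n0 = 1L, Np = 10L))
  c3 <- derive_counts(c(n1p = 2, n2p = 2, n3p = 2, n4p = 1, n5p = 1))
  expect_equal(c3, list(n2 = 2L, n1 = 4L, n0 = 7L, Np = 13L))
  set.seed(23)
  for (i in 1:200) {
    b <- setNames(rpois(5, c(1, 20, 3, 1, 0.5)),
                  c("n1p", "n2p", "n3p", "n4p", "n5p"))
    ct <- derive_counts(b)
    expect_identical(ct$n1 + ct$n2 + ct$n0, ct$Np)
  }
})

test_that("the three indices are percentages of N' and sum to 100", {
  expect_equal(unname(seeding_indices(list(n1 = 10, n2 = 0, n0 = 0, Np = 10))),
               c(100, 0, 0))
  expect_equal(unname(seeding_indices(list(n1 = 8, n2 = 1, n0 = 1, Np = 10))),
               c(80, 10, 10))
  idx <- seeding_indices(list(n1 = 4, n2 = 2, n0 = 7, Np = 13))
  expect_equal(unname(idx), c(400 / 13, 200 / 13, 700 / 13))
  expect_equal(sum(idx), 100)
  expect_error(seeding_indices(list(n1 = 0, n2 = 0, n0 = 0, Np = 0)),
               "no intervals")
})

test_that("qualified dispersion uses the population SD about the mean", {
  s <- qualified_stats(c(1, 1, 1))
  expect_equal(c(s$s_bar, s$sigma, s$cv), c(1, 0, 0))
  s2 <- qualified_stats(c(0.8, 1.0, 1.2))
  expect_equal(s2$s_bar, 1.0)
  expect_equal(s2$sigma, sqrt(0.08 / 3))
  expect_equal(s2$cv, 100 * sqrt(0.08 / 3))
  # single qualified value: no dispersion
  s3 <- qualified_stats(c(0.3, 1.0, 2.0))  # only 1.0 qualifies
  expect_equal(s3$n_qualified, 1L)
  expect_equal(s3$sigma, 0)
  # literal second-moment form, for auditing
  s4 <- qualified_stats(c(0.8, 1.0, 1.2), sigma_formula = "as_printed")
  expect_equal(s4$sigma, sqrt(sum(c(0.8, 1, 1.2)^2) / 3))
  # classical CV variant
  s5 <- qualified_stats(c(0.6, 0.8), cv_normalize_by_mean = TRUE)
  expect_equal(s5$cv, 100 * s5$sigma / 0.7)
  # no qualified ratio at all
  s6 <- qualified_stats(c(0.1, 3.9))
  expect_true(is.na(s6$cv))
})

test_that("full evaluation reproduces the hand-traced example", {
  rep <- evaluate_sowing(c(0.06, 0.16, 0.44, 0.20), target = 0.20)
  expect_equal(unname(rep$bins), c(1, 2, 1, 0, 0))
  expect_equal(rep$counts, list(n2 = 1L, n1 = 2L, n0 = 1L, Np = 4L))
  expect_equal(c(rep$qfi, rep$mul, rep$mi), c(50, 25, 25))
  expect_true(rep$valid)
})

test_that("degenerate spacing series are rejected", {
  expect_error(evaluate_sowing(numeric(0), 0.2), "empty")
  expect_error(evaluate_sowing(c(0.01, 0.02), 0.2), "no intervals")
  perfect <- evaluate_sowing(rep(0.2, 10), 0.2)
  expect_equal(c(perfect$qfi, perfect$mul, perfect$mi, perfect$cv),
               c(100, 0, 0, 0))
})

test_that("short-interval-dominated stands are flagged, not clamped", {
  # many multiples: n'1 large relative to the rest
  rep <- evaluate_sowing(c(rep(0.02, 5), 0.2), 0.2)
  expect_false(rep$valid)
  expect_lt(rep$qfi, 0)  # n1 < 0 reported as-is
  expect_match(paste(rep$warnings, collapse = " "), "n1 < 0")
})

test_that("evaluation is order-free in the spacing list", {
  set.seed(31)
  sp <- runif(60, 0.01, 0.7)
  r1 <- evaluate_sowing(sp, 0.2)
  r2 <- evaluate_sowing(sample(sp), 0.2)
  expect_identical(r1$bins, r2$bins)
  expect_identical(c(r1$qfi, r1$mul, r1$mi, r1$cv),
                   c(r2$qfi, r2$mul, r2$mi, r2$cv))
})

test_that("appending a far-miss ratio never decreases MI nor increases MUL", {
  set.seed(37)
  for (i in 1:40) {
    sp <- runif(sample(5:50, 1), 0.05, 0.7)
    base <- evaluate_sowing(sp, 0.2)
    ext <- evaluate_sowing(c(sp, 0.2 * runif(1, 3.51, 6)), 0.2)
    expect_gte(ext$mi, base$mi)
    expect_lte(ext$mul, base$mul)
  }
})

test_that("the report is invariant to a common unit rescaling", {
  set.seed(41)
  sp <- runif(80, 0.02, 0.8)
  ref <- evaluate_sowing(sp, 0.2)
  keep <- setdiff(names(unclass(ref)), "target")  # target echoes the input unit
  for (f in c(10, 100, 1000, 0.0254, pi, runif(5, 0.01, 50))) {
    scaled <- evaluate_sowing(sp * f, 0.2 * f)
    expect_identical(unclass(ref)[keep], unclass(scaled)[keep],
                     label = sprintf("factor %g", f))
  }
})
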