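test_that("Watson U2 statistic matches the pooled-order oracle", {
  s1 <- c(0.1, 0.2, 0.3)
  s2 <- c(3.1, 3.2, 3.3)
  expect_equal(watson_u2_statistic(s1, s2), oracle_wu2(s1, s2),
               tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    a <- runif(sample(3:12, 1), 0, 2 * pi)
    b <- runif(sample(3:12, 1), 0, 2 * pi)
    expect_equal(watson_u2_statistic(a, b), oracle_wu2(a, b),
                 tolerance = 1e-10)
    expect_equal(watson_u2_statistic(a, b), watson_u2_statistic(b, a),
                 tolerance = 1e-12)
    rot <- 1.234
    expect_equal(watson_u2_statistic(wrap_angle(a + rot), wrap_angle(b + rot)),
                 watson_u2_statistic(a, b), tolerance = 1e-12)
  }
  expect_error(watson_u2_statistic(0.5, 0.7), "at least 3")
  expect_error(watson_u2_statistic(c(0.5, 1), c(0.5, 2), ties = "error"),
               "ties")
  # default tie handling equals a literal infinitesimal offset on sample 2
  expect_equal(watson_u2_statistic(c(0.5, 1), c(0.5, 2)),
               oracle_wu2(c(0.5, 1), c(0.5, 2)), tolerance = 1e-10)
})

test_that("asymptotic Watson U2 tail matches the series and is monotone", {
  expect_equal(watson_u2_pvalue_asymptotic(0.5), oracle_wu2_tail(0.5),
               tolerance = 1e-9)
  expect_equal(watson_u2_pvalue_asymptotic(0.187), oracle_wu2_tail(0.187),
               tolerance = 1e-9)
  expect_equal(watson_u2_pvalue_asymptotic(0), 1)   # clamped at the limit
  expect_gt(watson_u2_pvalue_asymptotic(0.1), watson_u2_pvalue_asymptotic(0.2))
  expect_error(watson_u2_pvalue_asymptotic(-0.1), "non-negative")
})

test_that("Watson-Wheeler statistic matches the uniform-scores oracle", {
  # sample 1 at alternating pooled positions: zero resultant, W = 0
  w0 <- watson_wheeler_statistic(c(0.1, 0.5), c(0.3, 0.7))
  expect_equal(w0$statistic, 0, tolerance = 1e-12)
  expect_equal(w0$p_value, 1)

  w <- watson_wheeler_statistic(c(0.1, 0.2), c(3.0, 3.1))
  expect_equal(w$statistic, oracle_ww(c(0.1, 0.2), c(3.0, 3.1)),
               tolerance = 1e-12)
  expect_equal(w$p_value, pchisq(w$statistic, 2, lower.tail = FALSE))

  set.seed(31)
  for (i in 1:10) {
    a <- runif(sample(3:12, 1), 0, 2 * pi)
    b <- runif(sample(3:12, 1), 0, 2 * pi)
    expect_equal(watson_wheeler_statistic(a, b)$statistic,
                 oracle_ww(a, b), tolerance = 1e-10)
    expect_equal(watson_wheeler_statistic(a, b)$statistic,
                 watson_wheeler_statistic(b, a)$statistic, tolerance = 1e-10)
  }

  expect_error(watson_wheeler_statistic(c(0.5, 1), c(0.5, 2)), "ties")
  wj <- watson_wheeler_statistic(c(0.5, 1), c(0.5, 2), ties = "jitter")
  expect_true(is.finite(wj$statistic))
})

test_that("Rao spacing-frequencies statistic counts arc discrepancies", {
  # all four points of s2 land in one of s1's four arcs: f = (4,0,0,0)
  expect_equal(rao_spacing_frequency_statistic(c(0, pi / 2, pi, 3 * pi / 2),
                                               c(0.1, 0.2, 0.3, 0.4)), 6)
  # perfect interleaving: every arc holds exactly n/m points
  s1 <- (0:3) * pi / 2
  s2 <- s1 + pi / 4
  expect_equal(rao_spacing_frequency_statistic(s1, s2), 0)

  set.seed(41)
  for (i in 1:10) {
    a <- runif(sample(2:10, 1), 0, 2 * pi)
    b <- runif(sample(2:10, 1), 0, 2 * pi)
    expect_equal(rao_spacing_frequency_statistic(a, b), oracle_rsf(a, b))
  }
  expect_error(rao_spacing_frequency_statistic(0.3, c(1, 2)), "at least 2")

  set.seed(42)
  a <- runif(8, 0, 2 * pi); b <- runif(8, 0, 2 * pi)
  r1 <- rao_spacing_frequency_test(a, b, n_permutations = 299, seed = 5)
  rot <- 0.777
  r2 <- rao_spacing_frequency_test(wrap_angle(a + rot), wrap_angle(b + rot),
                                   n_permutations = 299, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("the C++ permutation engine reproduces the R statistics", {
  set.seed(51)
  for (i in 1:5) {
    a <- runif(sample(4:12, 1), 0, 2 * pi)
    b <- runif(sample(4:12, 1), 0, 2 * pi)
    expect_equal(unname(art_test(a, b, 9, seed = 1)$statistic),
                 art_statistic(a, b), tolerance = 1e-10)
    expect_equal(unname(watson_u2_test(a, b, "permutation", 9,
                                       seed = 1)$statistic),
                 watson_u2_statistic(a, b), tolerance = 1e-10)
    expect_equal(unname(watson_wheeler_test(a, b, "permutation", 9,
                                            seed = 1)$statistic),
                 watson_wheeler_statistic(a, b)$statistic, tolerance = 1e-10)
    expect_equal(unname(rao_spacing_frequency_test(a, b, 9,
                                                   seed = 1)$statistic),
                 rao_spacing_frequency_statistic(a, b), tolerance = 1e-10)
  }
})

test_that("pWU2 and pWW Monte-Carlo p-values match exhaustive enumeration", {
  set.seed(61)
  s1 <- runif(4, 0, 2 * pi)
  s2 <- wrap_angle(runif(4, 0, 2 * pi) + 1.5)
  nperm <- 10000
  for (case in list(
    list(stat = watson_u2_statistic,
         mc = watson_u2_test(s1, s2, "permutation", nperm, seed = 3)$p_value),
    list(stat = function(a, b) watson_wheeler_statistic(a, b)$statistic,
         mc = watson_wheeler_test(s1, s2, "permutation", nperm,
                                  seed = 3)$p_value))) {
    exact <- oracle_exhaustive_p(case$stat, s1, s2)
    se <- sqrt(exact * (1 - exact) / nperm)
    expect_lt(abs(case$mc - exact), 3 * se + 2 / nperm)
  }
})

test_that("run_test dispatches by name and rejects unknown names", {
  set.seed(71)
  a <- runif(8, 0, 2 * pi)
  b <- runif(8, 0, 2 * pi)
  r1 <- run_test("ART", a, b, n_permutations = 199, seed = 4)
  r2 <- art_test(a, b, n_permutations = 199, seed = 4)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$statistic, r2$statistic)

  for (nm in c("ART", "WU2", "pWU2", "WW", "pWW", "Rsf")) {
    r <- run_test(nm, a, b, n_permutations = 99, seed = 1)
    expect_s3_class(r, "circart_test")
    expect_identical(r$test_name, nm)
    expect_gte(unname(r$statistic), 0)
    expect_gt(r$p_value, 0)
    expect_lte(r$p_value, 1)
    expect_identical(r$method,
                     if (nm %in% c("WU2", "WW")) "asymptotic" else "permutation")
  }
  expect_error(run_test("XYZ", a, b), "valid names")
})
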