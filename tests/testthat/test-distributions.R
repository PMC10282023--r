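test_that("von Mises sampler: uniform limit, location and concentration", {
  set.seed(101)
  u <- sample_von_mises(0, 0, 10000)
  expect_true(all(u >= 0 & u < 2 * pi))
  d <- suppressWarnings(ks.test(as.numeric(u), "punif", 0, 2 * pi)$statistic)
  expect_lt(unname(d), 1.63 / sqrt(10000))  # 1% KS critical value

  set.seed(102)
  x <- sample_von_mises(pi / 3, 8, 10000)
  expect_true(all(x >= 0 & x < 2 * pi))
  expect_lt(abs(circ_mean(as.numeric(x)) - pi / 3), 0.05)
  # mean resultant length converges to the Bessel ratio I1(8)/I0(8)
  expect_lt(abs(resultant_length(as.numeric(x)) -
                besselI(8, 1) / besselI(8, 0)), 0.02)

  expect_error(sample_von_mises(0, -1, 10), ">= 0")
  expect_error(sample_von_mises(0, 2, 0), ">= 1")
})

test_that("samplers are deterministic and location equivariant", {
  set.seed(103)
  a <- sample_von_mises(1, 3, 50)
  set.seed(103)
  b <- sample_von_mises(1, 3, 50)
  expect_identical(as.numeric(a), as.numeric(b))

  shift <- 0.9
  set.seed(104); x0 <- sample_von_mises(0, 3, 100)
  set.seed(104); x1 <- sample_von_mises(shift, 3, 100)
  expect_equal(as.numeric(x1), wrap_angle(as.numeric(x0) + shift),
               tolerance = 1e-12)

  set.seed(105); w0 <- sample_wrapped_skew_normal(0, 1, 30, 100)
  set.seed(105); w1 <- sample_wrapped_skew_normal(shift, 1, 30, 100)
  expect_equal(as.numeric(w1), wrap_angle(as.numeric(w0) + shift),
               tolerance = 1e-12)

  set.seed(106); ax0 <- sample_axial_von_mises(0, 4, 100)
  set.seed(106); ax1 <- sample_axial_von_mises(shift, 4, 100)
  expect_equal(as.numeric(ax1), wrap_angle(as.numeric(ax0) + shift),
               tolerance = 1e-12)
})

test_that("axial von Mises mixes antipodal modes equally", {
  set.seed(111)
  x <- as.numeric(sample_axial_von_mises(0, 8, 10000))
  # the two modes cancel in the raw resultant ...
  expect_lt(resultant_length(x), 0.05)
  # ... while angle doubling folds the modes together: the doubled angles are
  # 2*VM(mu, kappa) mod 2pi, whose resultant is the second trigonometric
  # moment I2(kappa)/I0(kappa) of the von Mises distribution
  expect_lt(abs(resultant_length(wrap_angle(2 * x)) -
                besselI(8, 2) / besselI(8, 0)), 0.02)
  # and the doubled resultant is far above the raw one: the mixture is axial
  expect_gt(resultant_length(wrap_angle(2 * x)), 0.5)

  set.seed(112)
  u <- as.numeric(sample_axial_von_mises(1.1, 0, 10000))
  d <- suppressWarnings(ks.test(u, "punif", 0, 2 * pi)$statistic)
  expect_lt(unname(d), 1.63 / sqrt(10000))
  expect_error(sample_axial_von_mises(0, -0.5, 10), ">= 0")
})

test_that("wrapped skew-normal sampler follows the convolution construction", {
  # alpha = 0: symmetric; latent variable is plain normal
  set.seed(121)
  x <- as.numeric(sample_wrapped_skew_normal(pi, 0.1, 0, 10000))
  z <- (x - pi) / 0.1
  expect_lt(abs(sample_skewness(z)), 0.08)
  expect_lt(oracle_geodesic(circ_mean(x), pi), 0.02)

  # alpha = 30: latent skewness matches the closed-form moment formula
  set.seed(122)
  y <- as.numeric(sample_wrapped_skew_normal(pi, 0.05, 30, 100000))
  zl <- (y - pi) / 0.05
  expect_lt(abs(sample_skewness(zl) - skew_normal_skewness(30)), 0.05)

  set.seed(123)
  w <- sample_wrapped_skew_normal(0, 4, 30, 1000)
  expect_true(all(w >= 0 & w < 2 * pi))
  expect_error(sample_wrapped_skew_normal(0, 0, 1, 10), "> 0")
})

test_that("distribution_spec validates family parameters and samples", {
  vm <- distribution_spec("von_mises", mu = 0, kappa = 2)
  expect_match(format(vm), "VM")
  wsn <- distribution_spec("wrapped_skew_normal", xi = 0, rho = 2, alpha = 30)
  expect_match(format(wsn), "WSN")

  expect_error(distribution_spec("von_mises", mu = 0), "requires")
  expect_error(distribution_spec("von_mises", mu = 0, kappa = -1), ">= 0")
  expect_error(distribution_spec("von_mises", mu = 0, kappa = 1, rho = 2),
               "do not apply")
  expect_error(distribution_spec("wrapped_skew_normal", xi = 0, rho = 0,
                                 alpha = 1), "> 0")
  expect_error(distribution_spec("wrapped_skew_normal", xi = 0, rho = 1,
                                 alpha = 0, mu = 1), "do not apply")

  set.seed(131)
  s <- sample_angles(wsn, 25)
  expect_s3_class(s, "angle_sample")
  expect_length(as.numeric(s), 25)
})
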