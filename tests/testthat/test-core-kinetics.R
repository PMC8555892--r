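test_that("logistic_fraction matches its closed form and boundary cases", {
  # initial condition and no-replication limits
  expect_equal(logistic_fraction(0, 0.5, 0.01), 0.01)
  expect_equal(logistic_fraction(37, 0, 0.3), 0.3)
  # half-maximum time derived analytically: t_half = ln((1 - f0)/f0)/kappa
  t_half <- log((1 - 1e-4) / 1e-4) / 0.17
  expect_equal(logistic_fraction(t_half, 0.17, 1e-4), 0.5, tolerance = 1e-12)
  # bounded and monotone
  f <- logistic_fraction(seq(-50, 200, by = 1), 0.17, 1e-4)
  expect_true(all(f > 0 & f < 1))
  expect_true(all(diff(f) >= 0))
  expect_error(logistic_fraction(1, 0.1, 0), "f0")
  expect_error(logistic_fraction(1, 0.1, 1), "f0")
})

test_that("logistic_fraction satisfies the logistic ODE pointwise", {
  kappa <- 0.23; f0 <- 3e-4
  t <- seq(1, 80, by = 2.5)
  h <- 1e-5
  deriv <- (logistic_fraction(t + h, kappa, f0) -
              logistic_fraction(t - h, kappa, f0)) / (2 * h)
  f <- logistic_fraction(t, kappa, f0)
  expect_equal(deriv, kappa * f * (1 - f), tolerance = 1e-6)
})

test_that("signal map is affine with the stated range", {
  expect_equal(signal_from_fraction(0, 4, 1.06), 1.06)
  expect_equal(signal_from_fraction(1, 4, 1.06), 5.06)
  expect_equal(signal_from_fraction(0.5, 2, 0), 1)
  expect_error(signal_from_fraction(0.5, -1), "alpha")
})

test_that("doubling time is ln(2)/kappa and reproduces the headline values", {
  expect_equal(doubling_time(log(2)), 1)
  expect_equal(doubling_time(0.14), 4.951, tolerance = 1e-3)
  expect_equal(doubling_time(0.17), 4.077, tolerance = 1e-3)
  # doubling of the seed count in the exponential phase: f(t2)/f0 -> 2
  t2 <- doubling_time(0.3)
  expect_equal(logistic_fraction(t2, 0.3, 1e-8) / 1e-8, 2, tolerance = 1e-4)
  expect_error(doubling_time(0), "kappa")
})

test_that("fold increase over decades spans the expected 100-1000x range", {
  expect_equal(fold_increase(0.14, 0), 1)
  expect_equal(fold_increase(0.14, 33), exp(0.14 * 33))
  expect_gt(fold_increase(0.14, 33), 100)
  expect_lt(fold_increase(0.14, 49.3), 1000)
  expect_gt(fold_increase(0.14, 49.3), 900)
})

test_that("rate decomposition follows from kappa and mu and inverts exactly", {
  d <- decompose_rates(0.14, 1)
  expect_equal(d$k_growth, 0.14)
  expect_equal(d$k_mult, 0.14)
  d <- decompose_rates(0.14, 750)
  expect_equal(d$k_growth, 105)
  expect_equal(d$k_mult, 0.14 / 750)
  # identity decompose -> recombine over random draws
  withr::with_seed(42, {
    kappa <- 10^runif(1000, -3, 1)
    mu <- 10^runif(1000, 0, 4)
  })
  dec <- decompose_rates(kappa, mu)
  rec <- recombine_rates(dec$k_growth, dec$k_mult)
  expect_equal(rec$kappa, kappa, tolerance = 1e-9)
  expect_equal(rec$mu, mu, tolerance = 1e-9)
  expect_error(decompose_rates(-1, 10))
  expect_error(decompose_rates(0.1, 0.5))
})

test_that("fibril monomer count converts length through the layer spacing", {
  expect_equal(fibril_monomer_count(176), 749)
  expect_equal(signif(fibril_monomer_count(176), 2), 750)
  expect_equal(fibril_monomer_count(0.47), 2)
  expect_equal(fibril_monomer_count(4.7), 20)
  expect_error(fibril_monomer_count(-1))
})

test_that("critical diffusion reproduces the order-of-magnitude estimates", {
  expect_equal(critical_diffusion(1, 1), 0.0025)
  # regime-switch value for a 10 cm brain at the combined rate
  d_crit <- m2yr_to_m2s(critical_diffusion(0.14, 0.1))
  expect_gt(log10(d_crit), -13.5)
  expect_lt(log10(d_crit), -12.5)
  # best-fit ratio in region units: 0.1 * (6 regions)^2 * 0.14 ~ 0.5
  expect_equal(critical_diffusion(0.14, 6, ratio = 0.1), 0.504)
})

test_that("unit conversions are exact inverses", {
  x <- c(1e-13, 3.5e-6, 2.7)
  expect_equal(m2s_to_m2yr(m2yr_to_m2s(x)), x, tolerance = 1e-12)
  expect_equal(regions2_to_m2(m2_to_regions2(x, 0.02), 0.02), x, tolerance = 1e-12)
})

test_that("front speed is the geometric-mean pulled-front formula", {
  expect_equal(front_speed(1, 1), 2)
  expect_equal(front_speed(0.25, 1), 1)
  expect_error(front_speed(0, 1))
})

test_that("kinetic parameter bundles validate and serialise with units", {
  p <- kinetic_params(kappa = 0.17, f0 = 1e-4, alpha = 100, D = 0.5)
  expect_s3_class(p, "kinetic_params")
  expect_error(kinetic_params(kappa = -1), "kappa")
  expect_error(kinetic_params(kappa = 0.1, f0 = 2), "f0")
  json <- kinetic_params_json(p)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$kappa, 0.17)
  expect_equal(parsed$kappa_unit, "per_year")
  expect_equal(parsed$D_unit, "regions2_per_year")
})
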