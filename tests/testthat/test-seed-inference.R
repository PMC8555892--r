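test_that("noise SD pools log10 variability within replicate groups", {
  # two replicates at 10 and 1000: SD of (1, 3) = sqrt(2)
  d <- data.frame(subject = "a", region = "PV", time_years = 0,
                  value = c(10, 1000))
  expect_equal(estimate_noise_sd(d), sqrt(2))
  # identical replicates are degenerate
  d2 <- data.frame(subject = "a", region = "PV", time_years = 0,
                   value = c(5, 5))
  expect_warning(s <- estimate_noise_sd(d2), "degenerate")
  expect_equal(s, 0)
  # no replicates at all: instruct the user to set sigma explicitly
  d3 <- data.frame(subject = c("a", "b"), region = "PV",
                   time_years = c(0, 1), value = c(1, 2))
  expect_error(estimate_noise_sd(d3), "explicit")
  # recovery of a known lognormal noise scale from 200 replicate pairs
  withr::with_seed(3, {
    d4 <- data.frame(subject = rep(seq_len(200), each = 2),
                     region = "PV", time_years = 0,
                     value = 10^rnorm(400, 2, 0.3))
  })
  expect_equal(estimate_noise_sd(d4), 0.3, tolerance = 0.1)
})

test_that("the grid posterior normalises and reduces to the prior without data", {
  spec <- posterior_grid_spec(n_kappa = 40, n_f0 = 25, n_alpha = 15,
                              alpha_bounds = c(10, 1000))
  empty <- data.frame(time_years = numeric(), value = numeric())
  g <- posterior_grid(empty, sigma = 0.3, spec = spec)
  expect_equal(sum(g$mass), 1, tolerance = 1e-9)
  # 1/x priors on log axes: uniform over kappa and f0 cells; flat
  # alpha prior: mass proportional to cell width
  mk <- apply(g$mass, 1, sum)
  expect_equal(mk, rep(1 / 40, 40), tolerance = 1e-6)
  ma <- apply(g$mass, 3, sum)
  w <- diff(c(g$alpha_axis[1], (g$alpha_axis[-1] + head(g$alpha_axis, -1)) / 2,
              g$alpha_axis[15]))
  expect_equal(ma, w / sum(w), tolerance = 1e-9)
  # a single observation still yields a normalised posterior
  one <- data.frame(time_years = 10, value = 30)
  g1 <- posterior_grid(one, sigma = 0.3, spec = spec)
  expect_equal(sum(g1$mass), 1, tolerance = 1e-9)
})

test_that("the marginal kappa posterior concentrates on the generating rate", {
  kappa <- 0.17; f0 <- 1e-4; alpha <- 100; sigma <- 0.2
  t <- c(0, 21, 29, 34)
  withr::with_seed(21, {
    d <- data.frame(time_years = t,
                    value = eq_signal(t, kappa, f0, alpha) *
                      10^rnorm(4, 0, sigma))
  })
  post <- marginal_kappa(posterior_grid(d, sigma))
  s <- posterior_summary(post)
  expect_lt(abs(s$mean - kappa), s$sd)
  # doubling the noise SD widens the marginal
  post2 <- marginal_kappa(posterior_grid(d, 2 * sigma))
  expect_gt(posterior_summary(post2)$sd, s$sd)
})

test_that("marginalisation matches a Monte-Carlo oracle and trivial cases", {
  spec <- posterior_grid_spec(n_kappa = 30, n_f0 = 20, n_alpha = 10,
                              alpha_bounds = c(10, 1000))
  d <- data.frame(time_years = c(0, 10, 20, 30),
                  value = eq_signal(c(0, 10, 20, 30), 0.15, 1e-4, 50))
  g <- posterior_grid(d, sigma = 0.5, spec = spec)
  marg <- marginal_kappa(g)
  expect_equal(sum(marg$mass), 1, tolerance = 1e-9)
  # sampling oracle: draw cells from the joint, tabulate kappa indices
  withr::with_seed(8, {
    idx <- sample.int(length(g$mass), 1e6, replace = TRUE, prob = g$mass)
  })
  k_idx <- (idx - 1) %% 30 + 1
  mc <- tabulate(k_idx, 30) / 1e6
  expect_lt(sum(abs(mc - marg$mass)) / 2, 0.005)
  # delta-like joint: all mass at one kappa slice
  g2 <- g
  g2$mass[] <- 0
  g2$mass[17, 3, 2] <- 1
  m2 <- marginal_kappa(g2)
  expect_equal(m2$mass[17], 1)
})

test_that("combining posteriors multiplies densities", {
  axis <- seq(0.001, 0.5, length.out = 6000)
  flat <- kappa_posterior(axis, density = rep(1, 6000))
  p <- gaussian_posterior(0.17, 0.05, axis)
  comb_flat <- combine_marginals(list(p, flat))
  expect_equal(posterior_summary(comb_flat)$mean,
               posterior_summary(p)$mean, tolerance = 1e-6)
  # precision-weighted Gaussian product, closed form
  q <- gaussian_posterior(0.08, 0.02, axis)
  s <- posterior_summary(combine_marginals(list(p, q)))
  expect_equal(s$mean, 0.09241379, tolerance = 1e-3)
  expect_equal(s$sd, 0.01856953, tolerance = 1e-2)
  # K identical posteriors narrow the SD by ~ 1/sqrt(K)
  s4 <- posterior_summary(combine_marginals(list(p, p, p, p)))
  expect_equal(s4$sd, 0.05 / 2, tolerance = 0.01)
  # permutation invariance and associativity
  r <- gaussian_posterior(0.12, 0.03, axis)
  c1 <- combine_marginals(list(p, q, r))
  c2 <- combine_marginals(list(r, p, q))
  c3 <- combine_marginals(list(combine_marginals(list(p, q)), r))
  expect_equal(c1$mass, c2$mass, tolerance = 1e-12)
  expect_equal(c1$mass, c3$mass, tolerance = 1e-10)
  # disjoint supports carry no joint evidence
  lo <- kappa_posterior(axis, density = as.numeric(axis < 0.05))
  hi <- kappa_posterior(axis, density = as.numeric(axis > 0.3))
  expect_error(combine_marginals(list(lo, hi)), "support")
})

test_that("least-squares median fits recover the logistic parameters", {
  t <- c(0, 21, 29, 34)
  med <- eq_signal(t, 0.2, 1e-4, 50)
  fit <- lsq_median_fit(t, med)
  expect_equal(fit$kappa, 0.2, tolerance = 1e-3)
  expect_equal(fit$f0, 1e-4, tolerance = 0.01)
  expect_equal(fit$alpha, 50, tolerance = 0.01)
  # noisy medians still localise kappa
  withr::with_seed(13, {
    noisy <- med * 10^rnorm(4, 0, 0.05)
  })
  expect_equal(lsq_median_fit(t, noisy)$kappa, 0.2, tolerance = 0.1)
  # time translation leaves kappa unchanged and remaps f0 as the
  # logistic reparameterisation predicts
  shift <- 7
  fit2 <- lsq_median_fit(t + shift, med)
  expect_equal(fit2$kappa, fit$kappa, tolerance = 1e-3)
  f0s <- fit$f0 * exp(-fit$kappa * shift) /
    (1 - fit$f0 + fit$f0 * exp(-fit$kappa * shift))
  expect_equal(fit2$f0, f0s, tolerance = 0.01)
  expect_error(lsq_median_fit(c(0, 1), c(1, 2)), "3 distinct")
})

test_that("region-resolved inference combines per-region marginals", {
  d <- gen_seed_dataset(seed = 3)
  fit <- infer_kappa(d)
  expect_length(fit$per_region, 6)
  expect_named(fit$per_region)
  s <- fit$summary
  expect_true(s$ci_lower < s$mean && s$mean < s$ci_upper)
  expect_lt(abs(s$mean - 0.17), 3 * s$sd)
  # per-region combination equals the product of the marginals
  manual <- combine_marginals(fit$per_region)
  expect_equal(manual$mass, fit$combined$mass, tolerance = 1e-12)
  expect_true(all(c("region", "mean") %in% names(tidy(fit))))
})

test_that("credible intervals are calibrated on study-like cohorts", {
  hits <- vapply(1:100, function(i) {
    d <- gen_seed_dataset(seed = 1000 + i)
    s <- infer_kappa(d, sigma = 0.5)$summary
    s$mean - s$sd <= 0.17 && 0.17 <= s$mean + s$sd
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})
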