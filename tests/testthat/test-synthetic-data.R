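test_that("generators are pure functions of their seed", {
  expect_identical(gen_seed_dataset(seed = 9), gen_seed_dataset(seed = 9))
  expect_identical(gen_stage_age_table(seed = 9), gen_stage_age_table(seed = 9))
  expect_identical(gen_pet_cohort(seed = 9), gen_pet_cohort(seed = 9))
  expect_identical(gen_mouse_timecourses(seed = 9),
                   gen_mouse_timecourses(seed = 9))
  s1 <- gen_histology_image(seed = 9, width = 96, height = 96,
                            n_cells = 3, n_tau = 1)
  s2 <- gen_histology_image(seed = 9, width = 96, height = 96,
                            n_cells = 3, n_tau = 1)
  expect_identical(s1, s2)
  # different seeds change the data
  expect_false(identical(gen_seed_dataset(seed = 9),
                         gen_seed_dataset(seed = 10)))
})

test_that("noiseless seed data lie exactly on the logistic curves", {
  d <- gen_seed_dataset(seed = 2, sigma_log10 = 0, technical_replicates = 1)
  f0 <- 1e-3 * 0.3^(match(d$region, c("EC", "H", "PHG", "AC", "VA", "PV")) - 1)
  expect_equal(d$value, unname(eq_signal(d$time_years, 0.17, f0, 100)),
               tolerance = 1e-12)
  # study design: subject counts per stage and all six regions
  counts <- table(unique(d[, c("subject", "stage")])$stage)
  expect_equal(as.integer(counts[c("III", "IV", "V", "VI")]), c(7, 4, 6, 2))
  expect_equal(sort(unique(d$region)), sort(c("EC", "H", "PHG", "AC", "VA", "PV")))
  expect_error(gen_seed_dataset(seed = 1, subjects_per_stage = c(III = 0)),
               "positive")
})

test_that("generated seed data pass back through the inference", {
  # median posterior-mean error over replicate cohorts stays within 1 SD
  runs <- lapply(1:20, function(i) infer_kappa(gen_seed_dataset(seed = 600 + i),
                                               sigma = 0.5)$summary)
  within <- vapply(runs, function(s) abs(s$mean - 0.17) <= s$sd, logical(1))
  expect_gt(mean(within), 0.5)
})

test_that("stage-age tables honour their cohort size and truncation", {
  tab <- gen_stage_age_table(seed = 4)
  expect_equal(sum(tab$count), 2332, tolerance = 2)
  expect_true(all(tab$count >= 0))
  bins <- unique(tab$age_bin)
  expect_length(bins, 10)
  expect_equal(bins[10], "91-100")   # nothing beyond 100 years
  expect_setequal(unique(tab$stage), c("0", "I", "II", "III", "IV", "V", "VI"))
  # probabilities in the n -> infinity limit match the model
  p <- stage_age_probabilities(85.5)
  expect_equal(sum(p), 1)
  big <- gen_stage_age_table(seed = 5, n = 5e5,
                             decade_weights = c(rep(0, 8), 1, 0))
  got <- big$count[big$age_bin == "81-90"] / sum(big$count)
  expect_equal(got[match(colnames(p), big$stage[big$age_bin == "81-90"])],
               as.numeric(p), tolerance = 0.01)
})

test_that("noiseless PET cohorts sit exactly on the rate parabola", {
  d <- gen_pet_cohort(seed = 3, rate_noise_sd = 0)
  r <- annual_rate(d)
  expect_equal(r$rate, rate_model(d$S1, 0.17, 4, 1.06), tolerance = 1e-12)
  expect_equal(nrow(d), 101)
  expect_true(all(d$S1 >= 1.06 & d$S1 <= 1.06 + 0.8 * 4))
  expect_equal(as.integer(table(d$group)[c("AD", "MCI", "CN PiB+", "CN PiB-")]),
               c(4, 7, 27, 63))
})

test_that("noiseless mouse courses are straight lines in log space", {
  d <- gen_mouse_timecourses(seed = 3, sigma_ln = 0)
  for (r in unique(d$region)) {
    sub <- d[d$region == r, ]
    slopes <- diff(log(sub$value)) / diff(sub$time_months)
    expect_equal(slopes, rep(0.6, nrow(sub) - 1), tolerance = 1e-10)
  }
  # the default missing pattern leaves months 1-4 complete
  expect_equal(filter_complete_timepoints(d), 1:4)
})

test_that("generator outputs satisfy the consuming validations", {
  expect_silent(estimate_noise_sd(gen_seed_dataset(seed = 8)))
  expect_silent(conditional_stage_given_age(gen_stage_age_table(seed = 8)))
  expect_silent(annual_rate(gen_pet_cohort(seed = 8)))
  d <- gen_mouse_timecourses(seed = 8)
  expect_true(all(d$value > 0))
})
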