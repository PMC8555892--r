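test_that("geometries validate their invariants", {
  geo <- fkpp_geometry("interval", n_points = 101, r_max = 2)
  expect_equal(geo$spacing * (geo$n_points - 1), geo$r_max, tolerance = 1e-9)
  chain <- fkpp_geometry("region_chain")
  expect_equal(chain$n_points, 6L)
  expect_equal(chain$region_labels, c("EC", "H", "PHG", "AC", "VA", "PV"))
  expect_error(fkpp_geometry("region_chain", region_labels = c("a", "a")),
               "unique")
  expect_error(fkpp_geometry("interval", n_points = 1))
})

test_that("a uniform field follows the closed-form logistic exactly", {
  geo <- fkpp_geometry("interval", n_points = 101)
  tr <- fkpp_simulate(rep(0.01, 101), D = 0.3, kappa = 0.17, geo,
                      t_grid = seq(0, 30, by = 5))
  for (i in seq_along(tr$times)) {
    expect_equal(tr$profiles[i, ],
                 rep(logistic_fraction(tr$times[i], 0.17, 0.01), 101),
                 tolerance = 1e-5)
  }
})

test_that("pure diffusion conserves mass and relaxes to the spatial mean", {
  geo <- fkpp_geometry("interval", n_points = 101)
  ic <- bump_initial_condition(geo, amplitude = 0.8, width = 0.05)
  tr <- fkpp_simulate(ic, D = 0.02, kappa = 0, geo, c(0, 200))
  expect_equal(mean(tr$profiles[2, ]), mean(ic), tolerance = 1e-6)
  expect_lt(max(abs(tr$profiles[2, ] - mean(ic))), 1e-4)
})

test_that("solutions stay within [0, 1] and respect the comparison principle", {
  geo <- fkpp_geometry("interval", n_points = 81)
  withr::with_seed(7, {
    for (i in 1:5) {
      lo <- runif(81, 0, 0.4)
      hi <- lo + runif(81, 0, 0.5)
      tlo <- fkpp_simulate(lo, 0.01, 0.8, geo, seq(0, 6, by = 1))
      thi <- fkpp_simulate(hi, 0.01, 0.8, geo, seq(0, 6, by = 1))
      expect_true(all(tlo$profiles >= 0 & tlo$profiles <= 1 + 1e-9))
      expect_true(all(thi$profiles - tlo$profiles >= -1e-9))
    }
  })
})

test_that("an oversized user time step is rejected with the stable step", {
  geo <- fkpp_geometry("interval", n_points = 201)
  expect_error(
    fkpp_simulate(rep(0.01, 201), D = 0.01, kappa = 1, geo, c(0, 1), dt = 1),
    "maximum accurate step")
})

test_that("front speed agrees with 2 sqrt(D kappa) within 10%", {
  geo <- fkpp_geometry("interval", n_points = 201)
  for (D in c(0.01, 0.0025)) {
    ic <- front_initial_condition(geo, D, 1)
    horizon <- 0.85 / front_speed(D, 1)
    tr <- fkpp_simulate(ic, D, 1, geo, seq(0, horizon, length.out = 120))
    v <- measure_front_speed(tr)
    expect_equal(v, front_speed(D, 1), tolerance = 0.1)
  }
})

test_that("a front occupies the domain on the 1/(2 sqrt(D kappa)) time scale", {
  geo <- fkpp_geometry("interval", n_points = 201)
  D <- 0.025
  ic <- front_initial_condition(geo, D, 1, x0 = 0.05)
  tr <- fkpp_simulate(ic, D, 1, geo, seq(0, 6, length.out = 300))
  # time until every point exceeds 0.5, i.e. the front has swept the
  # remaining 95% of the interval
  t_occ <- min(tr$times[apply(tr$profiles, 1, min) >= 0.5])
  expect_equal(t_occ, 0.95 / (2 * sqrt(D)), tolerance = 0.15)
})

test_that("refining the discretisation leaves the solution unchanged", {
  geo1 <- fkpp_geometry("interval", n_points = 201)
  geo2 <- fkpp_geometry("interval", n_points = 401)
  D <- 0.005; kappa <- 1
  ic1 <- front_initial_condition(geo1, D, kappa)
  ic2 <- front_initial_condition(geo2, D, kappa)
  t_grid <- c(0, 2, 4)
  tr1 <- fkpp_simulate(ic1, D, kappa, geo1, t_grid)
  dt_fine <- taukinetics:::.fkpp_dt_max(D, kappa, geo1) / 2
  tr2 <- fkpp_simulate(ic2, D, kappa, geo2, t_grid, dt = dt_fine)
  expect_lt(max(abs(tr1$profiles[3, ] - tr2$profiles[3, seq(1, 401, by = 2)])),
            1e-3)
})

test_that("regime classification separates the limiting behaviours", {
  geo <- fkpp_geometry("interval", n_points = 201)
  # uniform initial condition: no spatial variation at all
  tru <- fkpp_simulate(rep(0.01, 201), 0.1, 1, geo, seq(0, 10, length.out = 60))
  cu <- classify_regime(tru)
  expect_equal(cu$label, "replication_limited")
  expect_equal(cu$chi, 0)
  # compact bump at the two published parameter ratios
  run_bump <- function(D_over_kappa) {
    ic <- bump_initial_condition(geo)
    classify_regime(fkpp_simulate(ic, D_over_kappa, 1, geo,
                                  seq(0, 60, length.out = 200)))
  }
  expect_equal(run_bump(0.00025)$label, "spreading_limited")
  expect_equal(run_bump(0.025)$label, "replication_limited")
  # never reaching half occupancy is inconclusive
  short <- fkpp_simulate(rep(0.01, 201), 0.1, 1, geo, c(0, 0.5))
  expect_error(classify_regime(short), "inconclusive")
})

test_that("the regime switch sits near D/kappa = 0.0025 r_max^2", {
  geo <- fkpp_geometry("interval", n_points = 201)
  ratios <- 0.0025 * c(1 / 9, 1 / 3, 1, 3)
  labels <- vapply(ratios, function(r) {
    ic <- bump_initial_condition(geo)
    classify_regime(fkpp_simulate(ic, r, 1, geo,
                                  seq(0, 60, length.out = 200)))$label
  }, character(1))
  expect_equal(labels[1], "spreading_limited")
  expect_equal(labels[4], "replication_limited")
  # the first replication-limited ratio lies within a factor 3 of 0.0025
  first_rep <- ratios[which(labels == "replication_limited")[1]]
  expect_gte(first_rep, 0.0025 / 3)
  expect_lte(first_rep, 0.0025 * 3)
})
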