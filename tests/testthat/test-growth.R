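test_that("competitive load matches direct evaluation of the kernel", {
  expect_equal(competition_load(100, c(90, 110, 120), 0), 1)
  expect_equal(competition_load(100, numeric(0), 0.05), 1)
  expect_equal(competition_load(100, 120, 0.05), exp(1))
  expect_equal(competition_load(120, 100, 0.05), exp(-1))
  expect_error(competition_load(100, 110, -0.1), "non-negative")
})

test_that("temperature response peaks at 15 C and hits 0.85 at the band edges", {
  expect_equal(temperature_response(15), 1)
  expect_equal(temperature_response(12), 0.85, tolerance = 1e-4)
  expect_equal(temperature_response(18), 0.85, tolerance = 1e-4)
  expect_equal(temperature_response(21), exp(-36 / 55.4))
  tt <- seq(12, 18, by = 0.1)
  expect_true(all(temperature_response(tt) >= 0.85 - 1e-4))
})

test_that("a day of growth respects the limits of the kernel", {
  lens <- c(60, 80, 100)
  expect_equal(daily_growth_step(lens, 15, 0.05, 0), lens)
  same <- rep(90, 5)
  out <- daily_growth_step(same, 15, 0.1, 2)
  expect_true(all(out == out[1]))  # exchangeability
  expect_gt(out[1], 90)
  out2 <- daily_growth_step(lens, 15, 0, 2)
  expect_true(all(out2 > lens))
})

test_that("the compiled simulation agrees with stepwise R recomputation", {
  lens <- c(90, 110)
  r_lens <- lens
  for (d in 1:30) r_lens <- daily_growth_step(r_lens, 15, 0.05, 1)
  c_lens <- simulate_growth(lens, rep(15, 30), 0.05, 1)
  expect_equal(c_lens, r_lens, tolerance = 1e-12)
})

test_that("the size gap between two fish widens monotonically", {
  lens <- c(90, 110)
  gaps <- numeric(30)
  for (d in 1:30) {
    lens <- daily_growth_step(lens, 15, 0.05, 1)
    gaps[d] <- diff(lens)
  }
  expect_true(all(diff(c(20, gaps)) > 0))
})

test_that("mass-length coupling is preserved through the simulation", {
  lens <- simulate_growth(c(30, 40, 55), rep(14, 100), 0.05, 2)
  mass <- 1e-5 * lens^3
  expect_equal((mass / 1e-5)^(1 / 3), lens, tolerance = 1e-9)
  expect_true(all(diff(rbind(c(30, 40, 55), lens)) > 0))  # no shrinking
})

test_that("symmetric competition generates no dispersion", {
  lens <- simulate_growth(rep(35, 20), rep(14, 150), 0, 3)
  expect_equal(sd(lens), 0)
})

test_that("stronger asymmetry strictly inflates final cohort spread", {
  init <- withr::with_seed(5, rnorm(100, 28, 2))
  sds <- vapply(c(0, 0.02, 0.05, 0.1), function(b) {
    sd(simulate_growth(init, rep(14, 167), b, 3))
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("fitting recovers known growth parameters (self-consistency)", {
  temps <- october_temps()
  init <- withr::with_seed(31, rnorm(200, 28, 2))
  truth <- c(beta = 0.06, eta_H = 3.5)
  oct <- simulate_growth(init, temps, truth["beta"], truth["eta_H"])
  fit <- fit_site_year(mean(oct), sd(oct), temps, seed = 2)
  expect_equal(unname(fit$params["beta"]), 0.06, tolerance = 0.2)
  expect_equal(unname(fit$params["eta_H"]), 3.5, tolerance = 0.1)
  expect_lt(fit$objective_value, 1e-4)
})

test_that("a sample with no dispersion inflation fits near-zero beta", {
  temps <- october_temps()
  init <- withr::with_seed(32, rnorm(200, 28, 2))
  oct <- simulate_growth(init, temps, 0, 2.5)
  fit <- fit_site_year(mean(oct), sd(oct), temps, seed = 3)
  expect_lt(unname(fit$params["beta"]), 0.01)
})

test_that("a larger observed mean refits to larger food availability", {
  temps <- october_temps()
  f1 <- fit_site_year(70, 8, temps, seed = 4)
  f2 <- fit_site_year(84, 8, temps, seed = 4)
  expect_gt(f2$params["eta_H"], f1$params["eta_H"])
})

test_that("April projection preserves the cohort and only adds growth", {
  temps <- october_temps()
  fit <- fit_site_year(78, 8, temps, seed = 5)
  winter <- rep(9, 168)
  apr <- project_to_april(fit, winter)
  expect_length(apr, length(fit$october_lengths))  # no overwinter deaths
  expect_true(all(apr >= fit$october_lengths))
  expect_gt(mean(apr), mean(fit$october_lengths))
  # zero food: April equals October exactly
  fit0 <- fit
  fit0$params["eta_H"] <- 0
  expect_equal(project_to_april(fit0, winter), fit$october_lengths)
})
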