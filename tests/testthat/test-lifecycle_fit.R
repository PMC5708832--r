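test_that("adult predictions follow the split-weighted lag arithmetic", {
  inputs <- cohort_inputs(year = 2000:2004, adults = rep(100, 5),
                          J = c(5000, 10000, 0, 0, 0),
                          C = rep(0, 5))
  pred <- predict_adults(inputs, c(0.01, 0), model = "fixed_rate")
  # year 2002: 0.01 * (0.53 * 10000 + 0.47 * 5000) = 76.5
  expect_equal(pred$predicted[pred$year == 2002], 76.5)
  # all-zero predictors give zero predictions
  p0 <- predict_adults(cohort_inputs(2000:2005, rep(0, 6), rep(0, 6),
                                     rep(0, 6), rep(0, 6), rep(0, 6)),
                       c(0.5, 0.5))
  expect_true(all(p0$predicted == 0))
})

test_that("prediction is exactly linear in the transition rates", {
  inputs <- make_cohort_inputs()
  qa <- c(0.8, 0.3); qb <- c(0.4, 1.1)
  pa <- predict_adults(inputs, qa)$predicted
  pb <- predict_adults(inputs, qb)$predicted
  pab <- predict_adults(inputs, qa + qb)$predicted
  expect_equal(pab, pa + pb, tolerance = 1e-12)
  expect_equal(predict_adults(inputs, 2 * qa)$predicted, 2 * pa,
               tolerance = 1e-12)
})

test_that("noise-free transition rates are recovered exactly", {
  q <- c(1.178, 0.594)
  inputs <- make_cohort_inputs(q = q, noise_sd = 0)
  fit <- fit_transition_rates(inputs, "size_conditional")
  expect_equal(unname(fit$q), q, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-12 * sum(inputs$adults^2))
  expect_equal(fit$k, 3)
  expect_equal(fit$n_years, 16)  # two lag years consumed
})

test_that("rates are unconstrained in sign and ratios are reportable", {
  q <- c(0.0076, -0.0433)
  inputs <- make_cohort_inputs(q = q, noise_sd = 0,
                               J_range = c(5e4, 5e5), C_range = c(2e3, 2e4))
  fit <- fit_transition_rates(inputs, "size_conditional")
  expect_equal(unname(fit$q), q, tolerance = 1e-8)
  expect_equal(unname(round(abs(fit$q[2]) / fit$q[1], 1)), 5.7)
})

test_that("an all-zero captive series drops its coefficient with a flag", {
  inputs <- make_cohort_inputs(q = c(1.2, 0))
  inputs$C <- 0
  inputs$C_star <- 0
  fit <- fit_transition_rates(inputs, "size_conditional")
  expect_true(is.na(fit$q[2]))
  expect_equal(fit$dropped, "q4")
  expect_equal(unname(fit$q[1]), 1.2, tolerance = 1e-9)
})

test_that("origin decomposition sums to the total prediction", {
  inputs <- make_cohort_inputs(q = c(1.1, 0.5), noise_sd = 80)
  fit <- fit_transition_rates(inputs, "size_conditional")
  dec <- decompose_origin(fit)
  expect_equal(dec$wild_pred + dec$captive_pred, dec$predicted,
               tolerance = 1e-10)
  # no captives: captive contribution is identically zero
  inputs0 <- make_cohort_inputs(q = c(1.1, 0))
  inputs0$C <- inputs0$C_star <- 0
  dec0 <- decompose_origin(fit_transition_rates(inputs0,
                                                "size_conditional"))
  expect_true(all(dec0$captive_pred == 0))
})

test_that("excluded years are removed from the fit", {
  inputs <- make_cohort_inputs(noise_sd = 10)
  fit_all <- fit_transition_rates(inputs, "size_conditional")
  fit_ex <- fit_transition_rates(inputs, "size_conditional",
                                 exclude_years = 2010)
  expect_equal(fit_ex$n_years, fit_all$n_years - 1)
  expect_false(2010 %in% fit_ex$predictions$year)
})

test_that("noisy replicates recover rates without systematic bias", {
  q <- c(1.178, 0.594)
  ests <- t(vapply(1:200, function(i) {
    fit <- fit_transition_rates(make_cohort_inputs(q = q, noise_sd = 100,
                                                   seed = i),
                                "size_conditional")
    unname(fit$q)
  }, numeric(2)))
  expect_equal(colMeans(ests), q, tolerance = 0.03)
})

test_that("the comparison table ranks both adult models", {
  inputs <- make_cohort_inputs(noise_sd = 50)
  cmp <- compare_lifecycle_models(inputs)
  expect_setequal(cmp$table$name, c("size_conditional", "fixed_rate"))
  expect_equal(cmp$table$k, c(3, 3))
  expect_equal(sum(cmp$table$weight), 1)
})
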