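test_that("recruitment predictions follow the model equations", {
  expect_equal(
    as.numeric(predict_recruitment("proportional", c(r = 270), 100)),
    27000)
  # logistic at r A = K / 2 gives K / 4
  K <- 282676; r <- 272.5
  A_half <- K / (2 * r)
  expect_equal(
    as.numeric(predict_recruitment("logistic_capacity", c(r = r, K = K),
                                   A_half)),
    K / 4)
  # low spawners: logistic is first-order proportional
  A_small <- 2
  expect_equal(
    as.numeric(predict_recruitment("logistic_capacity", c(r = r, K = K),
                                   A_small)),
    r * A_small, tolerance = r * A_small / K * 1.1)
  # translocation term is additive
  expect_equal(
    as.numeric(predict_recruitment("fixed_production_translocations",
                                   c(K = 1000, s = 0.5), 10, 200)),
    1100)
  # overshooting the capacity floors at zero with a flag
  p <- predict_recruitment("logistic_capacity", c(r = 100, K = 1000), 50)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "floored"))
})

test_that("fixed production fits the mean exactly", {
  d <- data.frame(J = c(10, 12, 14, 9, 15, 12), A = 1:6, R = rep(0, 6))
  fit <- fit_recruitment("fixed_production", d)
  expect_equal(unname(fit$params["K"]), mean(d$J))
  expect_equal(fit$k, 2)
})

test_that("model parameter counts match the family structure", {
  d <- withr::with_seed(2, data.frame(A = runif(18, 50, 800),
                                      R = runif(18, 1000, 30000)))
  d$J <- 200 * d$A * (1 - 200 * d$A / 3e5) + 1.5 * d$R +
    withr::with_seed(3, rnorm(18, 0, 5000))
  d$J <- pmax(d$J, 0)
  cmp <- compare_recruitment_models(d)
  ks <- setNames(cmp$table$k, cmp$table$name)
  expect_equal(unname(ks[c("fixed_production", "proportional")]), c(2, 2))
  expect_equal(unname(ks[c("fixed_production_translocations",
                           "proportional_translocations",
                           "logistic_capacity")]), c(3, 3, 3))
  expect_equal(unname(ks["logistic_capacity_translocations"]), 4)
  expect_equal(sum(cmp$table$weight), 1)
})

test_that("fitted parameters are locally least-squares optimal", {
  d <- withr::with_seed(4, data.frame(A = runif(18, 50, 800),
                                      R = rlnorm(18, log(15000), 0.4)))
  mu <- as.numeric(predict_recruitment(
    "logistic_capacity_translocations",
    c(r = 272.5, K = 282676, s = 1.9), d$A, d$R))
  d$J <- pmax(0, mu + withr::with_seed(5, rnorm(18, 0, 0.1 * mu)))
  fit <- fit_recruitment("logistic_capacity_translocations", d)
  rand <- withr::with_seed(6, cbind(r = runif(1000, 50, 1000),
                                    K = runif(1000, 5e4, 2e6),
                                    s = runif(1000, 0, 10)))
  rss_rand <- apply(rand, 1, function(p) {
    sum((d$J - predict_recruitment("logistic_capacity_translocations",
                                   p, d$A, d$R))^2)
  })
  expect_true(all(fit$rss <= rss_rand + 1e-6))
})

test_that("the logistic model degenerates to proportional as K grows", {
  A <- seq(10, 500, by = 10)
  p_prop <- as.numeric(predict_recruitment("proportional", c(r = 100), A))
  p_log <- as.numeric(predict_recruitment("logistic_capacity",
                                          c(r = 100, K = 1e12), A))
  expect_equal(p_log, p_prop, tolerance = 1e-6)
})

test_that("bias corrections reproduce the spatial-evenness arithmetic", {
  out <- bias_correct(c(r = 272.5, K = 282676, s = 1.9))
  expect_equal(round(unname(out$corrected["r"])), 193)
  expect_equal(round(unname(out$corrected["s"]), 2), 0.73)
  expect_equal(round(unname(out$corrected["K"]) / 1000) * 1000, 734000)
  expect_equal(round(out$expected_wild_transition, 2), 1.43)
})

test_that("bias correction round-trips", {
  p <- c(r = 272.5, K = 282676, s = 1.9)
  fwd <- bias_correct(p)$corrected
  back <- bias_correct(fwd, inverse = TRUE)$corrected
  expect_equal(back, p, tolerance = 1e-12)
})

test_that("a strong flow signal ranks the flow model first", {
  d <- withr::with_seed(8, {
    flow <- runif(18, 2, 25)
    data.frame(length_mm = 67.82 + 1.15 * flow + rnorm(18, 0, 3),
               adults = runif(18, 50, 800),
               translocations = runif(18, 1000, 30000),
               flow = flow)
  })
  res <- fit_length_models(d)
  expect_equal(res$table$name[1], "flow")
  slope <- coef(res$fits$flow)["flow"]
  expect_equal(unname(slope), 1.15, tolerance = 0.5)
  expect_true(all(res$table$k == c(3, 4, 4, 4, 3, 2, 3)[
    match(res$table$name, names(res$fits))]))
})

test_that("a pure-noise response leaves the intercept-only model in play", {
  near_top <- vapply(1:20, function(i) {
    d <- withr::with_seed(300 + i, data.frame(
      length_mm = rnorm(18, 75, 5),
      adults = runif(18, 50, 800),
      translocations = runif(18, 1000, 30000),
      flow = runif(18, 2, 25)))
    tab <- fit_length_models(d)$table
    tab$delta[tab$name == "intercept_only"] < 2
  }, logical(1))
  expect_gte(mean(near_top), 0.5)
})
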