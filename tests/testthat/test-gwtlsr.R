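test_that("exact covariates reduce GWTLSR to GWR at the same bandwidth", {
  sys <- random_system(12, m = 12, k = 2, eiv = FALSE)
  b <- 500
  g <- gwr_fit(sys, b)
  gt <- gwtlsr_fit(sys, b)
  expect_lt(max(abs(gt$coefficients - g$coefficients)), 1e-8)
  expect_lt(max(abs(gt$fitted - g$fitted)), 1e-8)
})

test_that("exact covariates plus a huge bandwidth reduce GWTLSR to OLS", {
  sys <- random_system(13, m = 10, k = 1, eiv = FALSE)
  o <- ols_fit(sys)
  gt <- gwtlsr_fit(sys, 1e8 * max(dist(sys$coords)))
  expect_lt(max(abs(sweep(gt$coefficients, 2, o$coefficients))), 1e-8)
})

test_that("every local solution keeps a zero intercept error column", {
  sys <- random_system(14, m = 10, k = 2)
  gt <- gwtlsr_fit(sys, 700)
  for (loc in gt$locals)
    expect_identical(max(abs(loc$E_A_tilde[, "(Intercept)"])), 0)
})

test_that("local EIV correction de-attenuates slopes relative to GWR", {
  # strong measurement noise attenuates GWR slopes toward zero; the
  # per-location WTLS step must recover magnitudes closer to the truth
  cfg <- sim_config(samples_per_station = 120, noise_ratio = 0.5, seed = 31)
  sim <- simulate_lur(cfg)
  sys <- as_design_system(sim$data)
  truth <- as.matrix(sim$truth[c("beta1", "beta2", "beta0")])
  b <- 4000
  g <- gwr_fit(sys, b)
  gt <- gwtlsr_fit(sys, b)
  err_slopes <- function(cf) sqrt(mean((cf[, 1:2] - truth[, 1:2])^2))
  expect_lt(err_slopes(gt$coefficients), err_slopes(g$coefficients))
})

test_that("the one-shot correction mode runs and differs from the fixed point", {
  sys <- random_system(15, m = 10, k = 1)
  one <- suppressWarnings(gwtlsr_fit(sys, 800, max_iter = 1L))
  full <- gwtlsr_fit(sys, 800)
  expect_false(all(one$converged))
  expect_true(all(full$converged))
  expect_false(isTRUE(all.equal(one$coefficients, full$coefficients,
                                tolerance = 1e-12)))
})

test_that("predictions at training stations reproduce fitted values in refit mode", {
  sim <- simulate_lur(sim_config(samples_per_station = 15, seed = 41))
  fit <- gwtls(y ~ f1 + f2, sim$data, method = "gwtlsr", bandwidth = 5000)
  pred <- predict(fit, sim$data, mode = "refit")
  expect_equal(pred, fitted(fit), tolerance = 1e-10)
})

test_that("all-zero covariates predict the local intercept", {
  sim <- simulate_lur(sim_config(samples_per_station = 15, seed = 42))
  fit <- gwtls(y ~ f1 + f2, sim$data, method = "gwtlsr", bandwidth = 5000)
  nd <- sim$data[1:3, ]
  nd$f1 <- 0; nd$f2 <- 0
  pred <- predict(fit, nd, mode = "nearest")
  expect_equal(unname(pred), unname(coef(fit)[1:3, "(Intercept)"]))
})

test_that("a constant coefficient surface predicts with the global line", {
  # noise-free constant-coefficient data: every local fit equals the global
  # one, so predictions anywhere follow the known line
  cfg <- sim_config(samples_per_station = 10, noise_ratio = 0, sigma_eps = 0,
                    surfaces = rep(list(list(type = "constant")), 3),
                    seed = 43)
  sim <- simulate_lur(cfg)
  fit <- gwtls(y ~ f1 + f2, sim$data, method = "gwtlsr", bandwidth = 5000)
  nd <- data.frame(u = c(1000, 19000), v = c(2000, 15000),
                   f1 = c(8, 14), f2 = c(9, 12))
  expect_equal(predict(fit, nd),
               5 + 2 * nd$f1 - 1 * nd$f2, tolerance = 1e-6)
})

test_that("prediction rejects covariate-schema mismatches", {
  sim <- simulate_lur(sim_config(samples_per_station = 15, seed = 44))
  fit <- gwtls(y ~ f1 + f2, sim$data, method = "gwtlsr", bandwidth = 5000)
  expect_error(predict(fit, sim$data[c("u", "v", "f1")]), "f2")
  expect_error(predict(fit, sim$data[c("f1", "f2")]), "coordinate")
})
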