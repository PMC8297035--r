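test_that("R-squared matches its definition and edge identities", {
  y <- c(1, 2, 5, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  # hand arithmetic: residual SS 1.5, total SS 6
  expect_equal(r_squared(c(0, 0, 3), c(-0.5, 1, 2.5)), 0.75)
  expect_error(r_squared(rep(2, 4), y), "constant")
})

test_that("R-squared is invariant to a common additive shift", {
  set.seed(10)
  y <- rnorm(20); yhat <- y + rnorm(20, sd = 0.3)
  expect_equal(r_squared(y + 17.3, yhat + 17.3), r_squared(y, yhat))
})

test_that("RMSE and MAE match hand-computed cases", {
  y <- c(1, 2, 3)
  expect_equal(rmse(y, y), 0)
  expect_equal(mae(y, y), 0)
  expect_equal(rmse(c(0, 0), c(1, -1)), 1)
  expect_equal(mae(c(0, 0), c(1, -1)), 1)
  expect_equal(mae(c(0, 0, 0), c(0.5, 1, 0.5)), 2 / 3)
  expect_equal(rmse(c(0, 0, 0), c(0.5, 1, 0.5)), sqrt(1.5 / 3))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("RMSE dominates MAE, with equality only for equal magnitudes", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    y <- rnorm(n); yhat <- y + rnorm(n)
    expect_gte(rmse(y, yhat), mae(y, yhat))
  }
  expect_equal(rmse(c(0, 0), c(2, -2)), mae(c(0, 0), c(2, -2)))
})

test_that("AICc follows the corrected-criterion formula", {
  # direct substitution: n = 10, sigma = 1, tr(S) = 2
  sys <- random_system(20, m = 10, k = 1, eiv = FALSE)
  fit <- list(residuals = rep(1, 10) * sqrt(1), hat_trace = 2)
  expect_equal(aicc(sys, fit), 10 * log(2 * pi) + 20)

  # larger trace at equal sigma -> larger AICc
  fit2 <- list(residuals = fit$residuals, hat_trace = 3)
  expect_gt(aicc(sys, fit2), aicc(sys, fit))

  # saturated trace is signaled, not silently returned
  fit3 <- list(residuals = fit$residuals, hat_trace = 8)
  expect_warning(v <- aicc(sys, fit3), "undefined")
  expect_identical(v, Inf)
})

test_that("AICc differences between models ignore the response units", {
  sys <- random_system(21, m = 12, k = 1, eiv = FALSE)
  f_a <- list(residuals = rnorm(12), hat_trace = 2)
  f_b <- list(residuals = rnorm(12), hat_trace = 4)
  d1 <- aicc(sys, f_a) - aicc(sys, f_b)
  scale_resid <- function(f) { f$residuals <- 1000 * f$residuals; f }
  d2 <- aicc(sys, scale_resid(f_a)) - aicc(sys, scale_resid(f_b))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("POD and POF classify 90th-percentile exceedances correctly", {
  y <- as.numeric(1:40)
  perfect <- pod_pof(y, y)
  expect_equal(perfect$pod, 1)
  expect_equal(perfect$pof, 0)

  # engineered counts a = 3, b = 1, c = 1
  est <- y; est[40] <- 0; est[5] <- 50
  pp <- pod_pof(y, est)
  expect_equal(unname(pp$counts), c(3, 1, 1))
  expect_equal(pp$pod, 0.75)
  expect_equal(pp$pof, 0.25)

  # constant prediction below threshold: no hits, no alarms
  pp0 <- suppressMessages(pod_pof(y, rep(0, 40)))
  expect_equal(pp0$pod, 0)
  expect_equal(pp0$pof, 0)

  # no observed exceedance -> POD undefined
  expect_warning(ppna <- pod_pof(rep(1, 10), rnorm(10)), "undefined")
  expect_true(is.na(ppna$pod))
})

test_that("Moran's I detects clustering and dispersion by direct formula", {
  # smooth distance-decaying surface on a grid: clustered
  g <- expand.grid(u = seq(0, 4000, by = 1000), v = seq(0, 4000, by = 1000))
  res <- exp(-((g$u - 2000)^2 + (g$v - 2000)^2) / 2e6)
  mi <- morans_i(res, as.matrix(g))
  expect_gt(mi$I, 0)
  expect_equal(mi$pattern, "Clustered")

  # cross-check the statistic itself against the direct-formula oracle
  D <- as.matrix(dist(g)); W <- 1 / D; diag(W) <- 0; W <- W / rowSums(W)
  expect_equal(mi$I, morans_i_direct(res, W), tolerance = 1e-12)

  # checkerboard signs with rook-contiguity weights: dispersed (negative)
  chk <- (-1)^(g$u / 1000 + g$v / 1000)
  rook <- (D > 0 & D <= 1000) * 1
  mi2 <- morans_i(chk, as.matrix(g), weights = rook)
  expect_lt(mi2$I, 0)
  expect_equal(mi2$pattern, "Dispersed")
})

test_that("the permutation mean of Moran's I is -1/(n-1)", {
  set.seed(12)
  coords <- cbind(runif(5, 0, 100), runif(5, 0, 100))
  res <- rnorm(5)
  perms <- combinat_perms(5)
  vals <- apply(perms, 1, function(p) morans_i(res[p], coords)$I)
  expect_equal(mean(vals), -1 / 4, tolerance = 1e-12)

  # sampled permutations at n = 30
  set.seed(13)
  coords30 <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  res30 <- rnorm(30)
  samp <- replicate(400, morans_i(sample(res30), coords30)$I)
  se <- sd(samp) / sqrt(length(samp))
  expect_lt(abs(mean(samp) - (-1 / 29)), 4 * se)
})

test_that("Moran's I inference agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(14)
  coords <- cbind(runif(12, 0, 1000), runif(12, 0, 1000))
  res <- rnorm(12)
  W <- 1 / as.matrix(dist(coords)); diag(W) <- 0
  ref <- ape::Moran.I(res, W)
  mi <- morans_i(res, coords)
  expect_equal(mi$I, ref$observed, tolerance = 1e-10)
  expect_equal(mi$expected, ref$expected, tolerance = 1e-12)
  expect_equal(mi$sd, ref$sd, tolerance = 1e-10)
  expect_equal(mi$p, ref$p.value, tolerance = 1e-8)
})

test_that("degenerate residual input is rejected and coincident points floored", {
  coords <- cbind(runif(6), runif(6))
  expect_error(morans_i(rep(1, 6), coords), "zero variance")
  coords2 <- coords; coords2[2, ] <- coords2[1, ]
  expect_warning(morans_i(rnorm(6), coords2), "coincident")
})
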