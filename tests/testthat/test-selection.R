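make_selection_data <- function(n = 60, seed = 51) {
  set.seed(seed)
  d <- data.frame(
    traffic_150 = rnorm(n), traffic_300 = rnorm(n),
    landuse_100 = rnorm(n), temp = rnorm(n), noise = rnorm(n))
  d$y <- 3 + 2 * d$traffic_150 + 1.5 * d$landuse_100 - d$temp +
    rnorm(n, sd = 0.5)
  d
}

test_that("Pearson screening ranks by |r| and keeps one buffer per base", {
  d <- make_selection_data()
  d$mirror <- d$y            # r = +1
  scr <- pearson_screen(d)
  expect_equal(scr$name[1], "mirror")
  expect_equal(scr$r[1], 1)

  # one buffer kept per base variable, the other discarded with a reason
  tr <- scr[scr$base == "traffic", ]
  expect_equal(sum(tr$kept), 1)
  expect_match(tr$reason[!tr$kept], "lower \\|r\\|")
})

test_that("|r| ties break toward the smaller buffer", {
  set.seed(52)
  d <- data.frame(u = 1:30, y = rnorm(30))
  d$f_500 <- d$y              # r = 1
  d$f_100 <- -d$y             # r = -1, same |r|
  scr <- pearson_screen(d, candidates = c("f_500", "f_100"))
  expect_equal(scr$name[scr$kept], "f_100")
})

test_that("orthogonal and constant candidates are handled", {
  d <- make_selection_data()
  # residualize a covariate against centered y: exactly zero correlation
  yc <- d$y - mean(d$y)
  v <- rnorm(60)
  d$ortho <- v - yc * sum(v * yc) / sum(yc^2)
  d$flat <- 5
  scr <- pearson_screen(d)
  expect_equal(scr$r[scr$name == "ortho"], 0, tolerance = 1e-12)
  expect_match(scr$reason[scr$name == "flat"], "zero variance")
  expect_false(scr$kept[scr$name == "flat"])
})

test_that("subset search finds the generating variables and drops pure noise", {
  d <- make_selection_data()
  sel <- subset_search(d, candidates = c("traffic_150", "landuse_100",
                                         "temp", "noise"))
  expect_setequal(sel$chosen, c("traffic_150", "landuse_100", "temp"))
  # the winning subset maximizes R^2 among significant subsets (oracle:
  # per-subset lm refits)
  surv <- sel$table[sel$table$significant, ]
  expect_equal(max(surv$r2),
               sel$table$r2[sel$table$variables ==
                              paste(sort(sel$chosen), collapse = "+")])
})

test_that("a single significant candidate is chosen as a singleton", {
  d <- make_selection_data()
  sel <- subset_search(d, candidates = "traffic_150")
  expect_equal(sel$chosen, "traffic_150")
})

test_that("the best-RMSE profile is non-increasing in subset size", {
  d <- make_selection_data()
  sel <- subset_search(d, candidates = c("traffic_150", "traffic_300",
                                         "landuse_100", "temp", "noise"))
  expect_true(all(diff(sel$rmse_profile$rmse) <= 1e-12))
})

test_that("oversized candidate pools are refused", {
  d <- make_selection_data()
  expect_error(subset_search(d, candidates = rep(names(d)[1:5], 3)),
               "12 candidates")
})

test_that("station-wise LOOCV partitions the data perfectly", {
  sim <- simulate_lur(sim_config(samples_per_station = 12, seed = 61))
  cv <- loocv_by_station(y ~ f1 + f2, sim$data, method = "ols")
  expect_equal(nrow(cv$folds), 9)
  expect_setequal(cv$folds$station, unique(sim$data$station_id))
  # every sample is tested exactly once and the fold sizes sum to the data
  expect_equal(sum(cv$folds$n_test), nrow(sim$data))
  expect_equal(cv$folds$n_test, rep(12, 9))
})

test_that("an oracle that knows the truth scores zero test error", {
  cfg <- sim_config(samples_per_station = 10, noise_ratio = 0, sigma_eps = 0,
                    surfaces = rep(list(list(type = "constant")), 3),
                    seed = 62)
  sim <- simulate_lur(cfg)
  cv <- loocv_by_station(y ~ f1 + f2, sim$data, method = "ols")
  expect_lt(max(cv$folds$rmse_test), 1e-8)
  expect_lt(max(cv$folds$mae_test), 1e-8)
})

test_that("LOOCV needs at least three stations", {
  sim <- simulate_lur(sim_config(samples_per_station = 10, seed = 63))
  two <- sim$data[sim$data$station_id %in% c("S01", "S02"), ]
  expect_error(loocv_by_station(y ~ f1 + f2, two, method = "ols"),
               "3 distinct stations")
})
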