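#' Configuration for the synthetic LUR generator
#'
#' Describes a synthetic monitoring-network study: stations scattered over a
#' square region, repeated samples per station, covariates observed with
#' known heteroscedastic measurement noise, and regression coefficient
#' surfaces that vary smoothly over space. Defaults emulate a small urban
#' PM2.5 network: 9 stations over a 20 km extent, 260 daily samples per
#' station (one season of daily means), two covariates (mean 10, sd 3),
#' base coefficients (2, −1) with
#' intercept 5, linear coefficient surfaces spanning ±50% of their mean
#' across the region, covariate noise at 30% of the covariate sd, and
#' observation noise of 2 µg/m³.
#'
#' Coefficient surfaces are specified per coefficient (intercept first) as
#' `list(type = "constant")`, `list(type = "linear", amplitude = 0.5)` (the
#' default: value = base × (1 + amplitude × t) with t the position along the
#' SW–NE diagonal scaled to \[−1, 1\]), or
#' `list(type = "gaussian", amplitude, center = c(u, v), scale)` (a bump:
#' value = base × (1 + amplitude × exp(−dist²/(2 scale²)))).
#'
#' @param n_stations number of stations (>= 3).
#' @param samples_per_station repeated observations per station.
#' @param extent side length of the square region in meters.
#' @param k number of covariates.
#' @param feature_means,feature_sds per-covariate mean and sd of the true
#'   covariate values (recycled to length k).
#' @param coef_base base (regional mean) coefficient per covariate
#'   (recycled); `intercept_base` likewise for the intercept.
#' @param intercept_base base intercept.
#' @param surfaces list of k+1 surface specs (intercept first); default all
#'   linear with amplitude 0.5.
#' @param noise_ratio measurement-noise ratio ρ: the per-covariate noise sd
#'   is ρ × covariate sd, so the variance δ² = (ρ sd)² (constant per
#'   covariate). Default 0.3.
#' @param sigma_eps observation noise sd (µg/m³).
#' @param seed integer seed; all randomness flows from it through named
#'   substreams (placement, features, feature noise, observation noise), so
#'   each component is independently reproducible.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_stations = 9, samples_per_station = 260,
                       extent = 20000, k = 2,
                       feature_means = c(10, 10), feature_sds = c(3, 3),
                       coef_base = c(2, -1), intercept_base = 5,
                       surfaces = NULL, noise_ratio = 0.3, sigma_eps = 2,
                       seed = 1L) {
  cfg <- list(
    n_stations = as.integer(n_stations),
    samples_per_station = as.integer(samples_per_station),
    extent = extent, k = as.integer(k),
    feature_means = rep_len(feature_means, k),
    feature_sds = rep_len(feature_sds, k),
    coef_base = rep_len(coef_base, k),
    intercept_base = intercept_base,
    surfaces = surfaces %||%
      rep(list(list(type = "linear", amplitude = 0.5)), k + 1),
    noise_ratio = noise_ratio, sigma_eps = sigma_eps,
    seed = as.integer(seed))

  problems <- character(0)
  if (cfg$n_stations < 3) problems <- c(problems, "n_stations must be >= 3")
  if (cfg$samples_per_station < 1)
    problems <- c(problems, "samples_per_station must be >= 1")
  if (cfg$extent <= 0) problems <- c(problems, "extent must be > 0")
  if (cfg$k < 1) problems <- c(problems, "k must be >= 1")
  if (any(cfg$feature_sds < 0)) problems <- c(problems, "feature_sds must be >= 0")
  if (cfg$noise_ratio < 0) problems <- c(problems, "noise_ratio must be >= 0")
  if (cfg$sigma_eps < 0) problems <- c(problems, "sigma_eps must be >= 0")
  if (length(cfg$surfaces) != cfg$k + 1)
    problems <- c(problems, "surfaces must have k + 1 entries (intercept first)")
  if (length(problems))
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "))
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate one coefficient surface at coordinates
surface_value <- function(base, spec, u, v, extent) {
  switch(spec$type,
    constant = rep(base, length(u)),
    linear = {
      amp <- spec$amplitude %||% 0.5
      t <- (u + v - extent) / extent   # SW-NE diagonal scaled to [-1, 1]
      base * (1 + amp * t)
    },
    gaussian = {
      amp <- spec$amplitude %||% 0.5
      ctr <- spec$center %||% c(extent / 2, extent / 2)
      scl <- spec$scale %||% (extent / 4)
      d2 <- (u - ctr[1])^2 + (v - ctr[2])^2
      base * (1 + amp * exp(-d2 / (2 * scl^2)))
    },
    stop("unknown surface type: ", spec$type))
}

# named substreams: each component draws under its own derived seed so that
# freezing one component does not perturb the others
substream_seed <- function(seed, name) {
  offset <- c(placement = 101L, features = 211L, feature_noise = 307L,
              observation_noise = 401L)[[name]]
  (seed * 7919L + offset) %% .Machine$integer.max
}

#' Generate a synthetic LUR dataset with known ground truth
#'
#' Places stations uniformly at random in the region, draws true covariate
#' values per sample, adds Gaussian measurement noise of known variance to
#' produce the *observed* covariates, evaluates the coefficient surfaces at
#' each station, and builds the response
#' \eqn{y_i = x_0(u_i,v_i) + \sum_k x_k(u_i,v_i)\,a_{ik} + \varepsilon_i}
#' from the *true* covariates plus observation noise. The observed table
#' carries the exact δ² used as `<feature>__var` columns, and the hidden
#' truth (noise-free covariates, local coefficients, noiseless response, and
#' every realized noise draw) is returned alongside, satisfying the exact
#' bookkeeping identity observed = truth + noise.
#'
#' @param config a [sim_config()].
#' @return list of class `lur_sim`: `data` (station table: station_id, u, v,
#'   y, f1..fk, f1__var..), `truth` (data frame with true features
#'   `f*_true`, noise draws `f*_noise`, local coefficients `beta0`,
#'   `beta1`.., `y_true`, `eps`), and `config`.
#' @export
simulate_lur <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$k
  ns <- config$n_stations
  spp <- config$samples_per_station
  m <- ns * spp

  set.seed(substream_seed(config$seed, "placement"))
  su <- stats::runif(ns, 0, config$extent)
  sv <- stats::runif(ns, 0, config$extent)

  station_id <- rep(sprintf("S%02d", seq_len(ns)), each = spp)
  u <- rep(su, each = spp); v <- rep(sv, each = spp)

  set.seed(substream_seed(config$seed, "features"))
  f_true <- sapply(seq_len(k), function(j)
    stats::rnorm(m, config$feature_means[j], config$feature_sds[j]))
  f_true <- matrix(f_true, nrow = m)

  delta <- config$noise_ratio * config$feature_sds     # per-feature noise sd
  set.seed(substream_seed(config$seed, "feature_noise"))
  f_noise <- sapply(seq_len(k), function(j) stats::rnorm(m, 0, delta[j]))
  f_noise <- matrix(f_noise, nrow = m)
  f_obs <- f_true + f_noise

  beta <- sapply(seq_len(k), function(j)
    surface_value(config$coef_base[j], config$surfaces[[j + 1]],
                  u, v, config$extent))
  beta <- matrix(beta, nrow = m)
  beta0 <- surface_value(config$intercept_base, config$surfaces[[1]],
                         u, v, config$extent)

  y_true <- beta0 + rowSums(beta * f_true)
  set.seed(substream_seed(config$seed, "observation_noise"))
  eps <- stats::rnorm(m, 0, config$sigma_eps)
  y <- y_true + eps

  fn <- paste0("f", seq_len(k))
  data <- data.frame(station_id = station_id, u = u, v = v, y = y,
                     stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    data[[fn[j]]] <- f_obs[, j]
    data[[paste0(fn[j], "__var")]] <- delta[j]^2
  }
  truth <- data.frame(station_id = station_id, u = u, v = v,
                      stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    truth[[paste0(fn[j], "_true")]] <- f_true[, j]
    truth[[paste0(fn[j], "_noise")]] <- f_noise[, j]
  }
  truth$beta0 <- beta0
  for (j in seq_len(k)) truth[[paste0("beta", j)]] <- beta[, j]
  truth$y_true <- y_true
  truth$eps <- eps

  structure(list(data = data, truth = truth, config = config),
            class = "lur_sim")
}

#' Coefficient- and prediction-recovery study across estimators
#'
#' Repeatedly simulates datasets from `config` (with per-replicate seeds
#' derived from `seed`), fits each requested estimator, and scores it on
#' coefficient recovery — the RMSE between the estimated local coefficient
#' vectors (global vectors, for OLS/WTLS) and the true local coefficients at
#' every sample — and, optionally, on held-station prediction via
#' station-wise leave-one-out cross-validation. This operationalizes an
#' estimator comparison on data where the truth is known.
#'
#' @param config a [sim_config()]; its `seed` is overridden per replicate.
#' @param estimators subset of `c("ols", "wtls", "gwr", "gwtlsr")`.
#' @param n_replicates number of simulated datasets (>= 2).
#' @param seed master seed for the replicate stream.
#' @param bandwidth bandwidth for the local estimators: `"aicc"` (default)
#'   selects per replicate by AICc on the GWR profile (shared with GWTLSR so
#'   the two see the same smoothing), or a number in meters.
#' @param prediction if `TRUE` (default), also run station-wise LOOCV per
#'   replicate and report test-prediction RMSE.
#' @return list of class `recovery_study`: `summary` (per estimator: mean
#'   and sd of coefficient RMSE and, if requested, prediction RMSE, plus a
#'   failure count), `replicates` (the full per-replicate table).
#' @export
recovery_study <- function(config, estimators = c("ols", "gwr", "gwtlsr"),
                           n_replicates = 20, seed = 1L, bandwidth = "aicc",
                           prediction = TRUE) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  estimators <- match.arg(estimators,
                          c("ols", "wtls", "gwr", "gwtlsr"), several.ok = TRUE)
  fml_for <- function(cfg) stats::reformulate(paste0("f", seq_len(cfg$k)),
                                              response = "y")
  rows <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- (seed * 1009L + r) %% .Machine$integer.max
    sim <- simulate_lur(cfg)
    truth_coef <- as.matrix(
      sim$truth[c(paste0("beta", seq_len(cfg$k)), "beta0")])
    fml <- fml_for(cfg)

    bw <- bandwidth
    if (identical(bandwidth, "aicc") &&
        any(estimators %in% c("gwr", "gwtlsr"))) {
      sys_r <- as_design_system(sim$data)
      bw <- select_bandwidth(sys_r, "gwr")$bandwidth
    }

    for (est in estimators) {
      res <- tryCatch({
        fit <- gwtls(fml, sim$data, method = est,
                     bandwidth = if (est %in% c("gwr", "gwtlsr")) bw else NULL)
        cf <- coef(fit)
        if (!is.matrix(cf))
          cf <- matrix(cf, nrow(truth_coef), length(cf), byrow = TRUE)
        coef_rmse <- sqrt(mean((cf - truth_coef)^2))
        pred_rmse <- NA_real_
        if (prediction) {
          cv <- suppressWarnings(loocv_by_station(
            fml, sim$data, method = est,
            bandwidth = if (est %in% c("gwr", "gwtlsr")) bw else NULL))
          pred_rmse <- unname(cv$mean["rmse_test"])
        }
        data.frame(replicate = r, estimator = est, coef_rmse = coef_rmse,
                   pred_rmse = pred_rmse, failed = FALSE,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warning("replicate ", r, ", estimator ", est, " failed: ",
                conditionMessage(e))
        data.frame(replicate = r, estimator = est, coef_rmse = NA_real_,
                   pred_rmse = NA_real_, failed = TRUE,
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$estimator), function(d) {
    ok <- !d$failed
    data.frame(estimator = d$estimator[1], n_ok = sum(ok),
               n_failed = sum(!ok),
               coef_rmse_mean = mean(d$coef_rmse[ok]),
               coef_rmse_sd = stats::sd(d$coef_rmse[ok]),
               pred_rmse_mean = mean(d$pred_rmse[ok]),
               pred_rmse_sd = stats::sd(d$pred_rmse[ok]),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(match(summ$estimator, estimators)), ]
  rownames(summ) <- NULL
  structure(list(summary = summ, replicates = reps),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat("Estimator recovery study (", max(x$replicates$replicate),
      "replicates )\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
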