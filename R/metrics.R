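#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i(\hat{y}_i - y_i)^2 / \sum_i(y_i - \bar{y})^2}.
#'
#' @param observed,estimated numeric vectors of equal length (>= 2).
#' @return scalar; 1 for a perfect fit, 0 for predicting the mean.
#' @export
r_squared <- function(observed, estimated) {
  stopifnot(length(observed) == length(estimated), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed series is constant; R-squared is undefined")
  1 - sum((estimated - observed)^2) / ss_tot
}

#' Root mean squared error and mean absolute error
#'
#' RMSE \eqn{= \sqrt{\frac{1}{n}\sum_i(\hat{y}_i - y_i)^2}} and
#' MAE \eqn{= \frac{1}{n}\sum_i|y_i - \hat{y}_i|}, both with divisor n.
#'
#' @param observed,estimated numeric vectors of equal, nonzero length.
#' @return scalar error in the units of the response (µg/m³ for PM2.5).
#' @export
rmse <- function(observed, estimated) {
  stopifnot(length(observed) == length(estimated))
  if (length(observed) == 0) stop("empty input")
  sqrt(mean((estimated - observed)^2))
}

#' @rdname rmse
#' @export
mae <- function(observed, estimated) {
  stopifnot(length(observed) == length(estimated))
  if (length(observed) == 0) stop("empty input")
  mean(abs(observed - estimated))
}

#' Corrected Akaike information criterion for a fitted model
#'
#' \deqn{AICc = 2 n \ln\hat\sigma + n \ln 2\pi +
#'   n\frac{n + tr(S)}{n - 2 - tr(S)}}
#' with \eqn{\hat\sigma = \sqrt{RSS/n}} (maximum-likelihood scale) and
#' \eqn{tr(S)} the trace of the hat matrix, i.e. the effective number of
#' parameters of the (possibly local) regression. For GWR the hat rows are
#' \eqn{r_i = A(i,:) (A^T W_i A)^{-1} A^T W_i}; for GWTLSR the corrected
#' design \eqn{\tilde A} and combined covariance \eqn{Q_{\tilde y}} take the
#' roles of \eqn{A} and \eqn{W^{-1}}; for the global fits \eqn{tr(S)} equals
#' the number of model columns.
#'
#' @param system the [design_system()] the model was fitted to.
#' @param fit a fit object from [ols_fit()], [gwr_fit()], [wtls_fit()] or
#'   [gwtlsr_fit()], fitted at the data's own coordinates.
#' @return scalar AICc; smaller is better.
#' @export
aicc <- function(system, fit) {
  n <- length(system$y)
  resid <- fit$residuals
  tr_s <- if (!is.null(fit$hat_trace)) fit$hat_trace else ncol(system$A)
  sigma_hat <- sqrt(sum(resid^2) / n)
  aicc_value(n, sigma_hat, tr_s)
}

# Eq.-level AICc kernel shared with the bandwidth search
aicc_value <- function(n, sigma_hat, tr_s) {
  if (tr_s >= n - 2) {
    warning("hat-matrix trace ", format(tr_s),
            " >= n - 2; AICc is undefined (returning Inf)")
    return(Inf)
  }
  2 * n * log(sigma_hat) + n * log(2 * pi) + n * (n + tr_s) / (n - 2 - tr_s)
}

#' Probability of detection and of false alarm for threshold exceedances
#'
#' Classifies each pair of observed/estimated values against the 90th
#' percentile of the observed series (linear interpolation between order
#' statistics) and counts: `a` joint exceedances (hits), `b` missed
#' exceedances (observed high, estimated low), `c` false exceedances
#' (estimated high, observed low). Then \eqn{POD = a/(a+b)} and
#' \eqn{POF = c/(a+c)}. A perfect prediction has POD = 1 and POF = 0.
#'
#' If no exceedance is observed (`a + b = 0`) POD is undefined and returned
#' as `NA` with a warning; if nothing is estimated above threshold
#' (`a + c = 0`) there are no alarms so POF is 0 (noted via `message()`).
#'
#' @param observed,estimated numeric vectors of equal length.
#' @param percentile exceedance percentile of the observed series; default 90.
#' @return list with `pod`, `pof`, `threshold`, and `counts` (a, b, c).
#' @export
pod_pof <- function(observed, estimated, percentile = 90) {
  stopifnot(length(observed) == length(estimated), length(observed) >= 1)
  thr <- stats::quantile(observed, percentile / 100, names = FALSE)
  obs_hi <- observed > thr
  est_hi <- estimated > thr
  a <- sum(obs_hi & est_hi)
  b <- sum(obs_hi & !est_hi)
  c_ <- sum(!obs_hi & est_hi)
  pod <- if (a + b == 0) {
    warning("no observed exceedances; POD is undefined")
    NA_real_
  } else a / (a + b)
  pof <- if (a + c_ == 0) {
    message("no estimated exceedances; POF set to 0 (no alarms, none false)")
    0
  } else c_ / (a + c_)
  list(pod = pod, pof = pof, threshold = thr,
       counts = c(a = a, b = b, c = c_))
}

#' Global Moran's I of model residuals
#'
#' Spatial autocorrelation of residuals with row-standardized
#' inverse-Euclidean-distance weights (zero diagonal). Inference uses the
#' randomization-moments approximation: the null mean is \eqn{-1/(n-1)} and
#' the variance involves the weight sums \eqn{S_0, S_1, S_2} and the sample
#' kurtosis. Residuals significantly clustered in space indicate the model
#' has left spatial structure unexplained.
#'
#' @param residuals numeric vector of residuals, one per location.
#' @param coords m×2 matrix of projected coordinates (meters).
#' @param weights optional m×m spatial weight matrix overriding the default
#'   inverse-distance scheme (will be zero-diagonaled and row-standardized).
#' @return list with `I`, `expected` (\eqn{-1/(n-1)}), `sd`, `z`, `p`
#'   (two-sided), and `pattern`: `"Clustered"` (z > 1.96), `"Dispersed"`
#'   (z < -1.96) or `"Random"`.
#' @export
morans_i <- function(residuals, coords, weights = NULL) {
  n <- length(residuals)
  if (n < 4) stop("Moran's I needs at least 4 locations")
  z <- residuals - mean(residuals)
  if (all(z == 0)) stop("residuals have zero variance; Moran's I is undefined")

  if (is.null(weights)) {
    D <- as.matrix(stats::dist(as.matrix(coords)))
    off <- D[upper.tri(D)]
    if (any(off == 0)) {
      floor_d <- if (any(off > 0)) min(off[off > 0]) * 1e-6 else 1
      warning("coincident locations; applying a distance floor of ",
              format(floor_d), " m")
      D[D == 0] <- floor_d
    }
    W <- 1 / D
  } else {
    W <- as.matrix(weights)
    stopifnot(all(dim(W) == n))
  }
  diag(W) <- 0
  rs <- rowSums(W)
  if (any(rs == 0)) stop("a location has no neighbors with positive weight")
  W <- W / rs

  s0 <- sum(W)
  i_obs <- (n / s0) * sum(W * tcrossprod(z)) / sum(z^2)

  e_i <- -1 / (n - 1)
  s1 <- 0.5 * sum((W + t(W))^2)
  s2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- (sum(z^4) / n) / (sum(z^2) / n)^2
  var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
              b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - e_i^2
  sd_i <- sqrt(var_i)
  zscore <- (i_obs - e_i) / sd_i
  pval <- 2 * stats::pnorm(-abs(zscore))
  pattern <- if (zscore > 1.96) "Clustered"
             else if (zscore < -1.96) "Dispersed"
             else "Random"
  list(I = i_obs, expected = e_i, sd = sd_i, z = zscore, p = pval,
       pattern = pattern)
}

#' Full assessment report for a fitted model
#'
#' Computes every assessment statistic at once: R², RMSE, MAE, AICc (with
#' \eqn{\hat\sigma} and tr(S)), POD/POF at the 90th-percentile threshold, and
#' residual Moran's I. When several observations share a station, Moran's I
#' is computed on station-mean residuals at the station coordinates
#' (coincident points carry no spatial information for a global statistic).
#'
#' @param system the fitted [design_system()].
#' @param fit a fit object carrying `fitted` and `residuals`.
#' @param percentile exceedance percentile for POD/POF.
#' @return object of class `metrics_report` (a list).
#' @export
metrics_report <- function(system, fit, percentile = 90) {
  y <- system$y
  yhat <- fit$fitted
  n <- length(y)
  tr_s <- if (!is.null(fit$hat_trace)) fit$hat_trace else ncol(system$A)
  pp <- pod_pof(y, yhat, percentile)

  key <- paste(system$coords[, 1], system$coords[, 2], sep = "\r")
  grp <- match(key, unique(key))
  res_station <- tapply(fit$residuals, grp, mean)
  coords_station <- system$coords[!duplicated(key), , drop = FALSE]
  mi <- if (length(res_station) >= 4 && stats::var(res_station) > 0)
    morans_i(as.numeric(res_station), coords_station)
  else list(I = NA_real_, expected = NA_real_, sd = NA_real_, z = NA_real_,
            p = NA_real_, pattern = NA_character_)

  structure(
    list(r2 = r_squared(y, yhat), rmse = rmse(y, yhat), mae = mae(y, yhat),
         aicc = aicc(system, fit), sigma_hat = sqrt(sum(fit$residuals^2) / n),
         hat_trace = tr_s, pod = pp$pod, pof = pp$pof,
         threshold = pp$threshold, counts = pp$counts,
         morans_i = mi$I, morans_z = mi$z, morans_p = mi$p,
         morans_pattern = mi$pattern, n = n),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Model assessment (n =", x$n, ")\n")
  cat(sprintf("  R2        %8.4f\n", x$r2))
  cat(sprintf("  RMSE      %8.4f\n", x$rmse))
  cat(sprintf("  MAE       %8.4f\n", x$mae))
  cat(sprintf("  AICc      %8.2f  (sigma_hat %.4f, tr(S) %.2f)\n",
              x$aicc, x$sigma_hat, x$hat_trace))
  cat(sprintf("  POD       %8.3f   POF %8.3f  (90th-pct threshold %.3f)\n",
              x$pod, x$pof, x$threshold))
  if (!is.na(x$morans_i))
    cat(sprintf("  Moran's I %8.3f  (z %.2f, p %.3f, %s)\n",
                x$morans_i, x$morans_z, x$morans_p, x$morans_pattern))
  invisible(x)
}
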