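#' Fit a spatial (errors-in-variables) land use regression model
#'
#' The main entry point of the package: a formula + data interface over the
#' four estimators. `method = "ols"` is a global equal-weight fit;
#' `"wtls"` is a global weighted total least squares fit acknowledging
#' measurement error in the covariates; `"gwr"` estimates spatially varying
#' coefficients with Gaussian kernel weights; `"gwtlsr"` (the default)
#' combines the two, solving the weighted total least squares problem at
#' every location with the kernel weights as response covariance.
#'
#' @param formula model formula, e.g. `y ~ traffic + temperature`. The
#'   intercept is always included (it is the trailing design column).
#' @param data data frame holding the response, covariates, coordinate
#'   columns, and optionally `<covariate>__var` measurement-variance columns.
#' @param coords either a two-sided formula naming the coordinate columns
#'   (default `~ u + v`) or an m×2 matrix of projected coordinates in meters.
#' @param method one of `"gwtlsr"`, `"gwr"`, `"wtls"`, `"ols"`.
#' @param variances per-cell covariate measurement variances: `NULL` (use
#'   `<covariate>__var` columns when present, else 0), a single value, a
#'   per-covariate vector, or a full matrix.
#' @param var_y response variances (default 1; ignored by the
#'   geographically weighted methods, which derive it from the kernel).
#' @param bandwidth kernel bandwidth in meters, or `"aicc"` (default for the
#'   local methods) to select it by minimizing AICc.
#' @param tol,max_iter convergence controls for the WTLS iteration.
#' @return object of class `gwtls` with the usual accessors: [coef()],
#'   [fitted()], [residuals()], [predict.gwtls()], [summary.gwtls()],
#'   [plot.gwtls()].
#' @examples
#' sim <- simulate_lur(sim_config(seed = 1))
#' fit <- gwtls(y ~ f1 + f2, data = sim$data, method = "gwtlsr")
#' summary(fit)
#' @export
gwtls <- function(formula, data, coords = ~ u + v,
                  method = c("gwtlsr", "gwr", "wtls", "ols"),
                  variances = NULL, var_y = 1, bandwidth = NULL,
                  tol = 1e-10, max_iter = 100L) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  features <- attr(stats::terms(formula, data = data), "term.labels")
  X <- as.matrix(data[features])

  if (inherits(coords, "formula")) {
    cn <- all.vars(coords)
    if (length(cn) != 2) stop("coords formula must name exactly two columns")
    cmat <- cbind(data[[cn[1]]], data[[cn[2]]])
  } else {
    cn <- c("u", "v")
    cmat <- as.matrix(coords)
  }

  if (is.null(variances)) {
    vcols <- paste0(features, "__var")
    variances <- matrix(0, nrow(X), ncol(X), dimnames = list(NULL, features))
    for (j in seq_along(features))
      if (vcols[j] %in% names(data)) variances[, j] <- data[[vcols[j]]]
  }
  system <- design_system(X, y, cmat, var_x = variances, var_y = var_y)

  local <- method %in% c("gwr", "gwtlsr")
  bw_profile <- NULL
  if (local) {
    if (is.null(bandwidth) || identical(bandwidth, "aicc")) {
      sel <- if (method == "gwr") select_bandwidth(system, "gwr")
             else select_bandwidth(system, "gwtlsr", tol = tol,
                                   max_iter = max_iter)
      bandwidth <- sel$bandwidth
      bw_profile <- sel$profile
    }
  }

  fit <- switch(method,
    ols = ols_fit(system),
    wtls = wtls_fit(system, tol = tol, max_iter = max_iter),
    gwr = gwr_fit(system, bandwidth = bandwidth),
    gwtlsr = gwtlsr_fit(system, bandwidth = bandwidth, tol = tol,
                        max_iter = max_iter))

  structure(
    list(call = match.call(), method = method, formula = formula,
         features = features, coord_names = cn, system = system, fit = fit,
         bandwidth = if (local) bandwidth else NA_real_,
         bandwidth_profile = bw_profile,
         tol = tol, max_iter = max_iter),
    class = "gwtls"
  )
}

#' @export
print.gwtls <- function(x, ...) {
  cat("Spatial LUR model fit —", toupper(x$method), "\n")
  cat("Call: "); print(x$call)
  cat("Observations:", length(x$system$y),
      " Covariates:", paste(x$features, collapse = ", "), "\n")
  if (!is.na(x$bandwidth))
    cat(sprintf("Kernel bandwidth: %.1f m (fixed Gaussian)\n", x$bandwidth))
  cf <- coef(x)
  if (is.matrix(cf)) {
    cat("Local coefficients (summary over regression points):\n")
    print(t(apply(cf, 2, stats::quantile,
                  probs = c(0.25, 0.5, 0.75), names = TRUE)))
  } else {
    cat("Coefficients:\n")
    print(cf)
  }
  invisible(x)
}

#' @export
coef.gwtls <- function(object, ...) object$fit$coefficients

#' @export
fitted.gwtls <- function(object, ...) object$fit$fitted

#' @export
residuals.gwtls <- function(object, ...) object$fit$residuals

#' Summarize a fitted spatial LUR model
#'
#' @param object a [gwtls()] fit.
#' @param percentile exceedance percentile for POD/POF (default 90).
#' @param ... unused.
#' @return object of class `summary.gwtls`: the fit plus a
#'   [metrics_report()].
#' @export
summary.gwtls <- function(object, percentile = 90, ...) {
  structure(
    list(fit = object,
         metrics = metrics_report(object$system, object$fit, percentile)),
    class = "summary.gwtls"
  )
}

#' @export
print.summary.gwtls <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$metrics)
  invisible(x)
}

#' Predict at new locations
#'
#' For the geographically weighted methods, coefficients at a new site are
#' either refitted there (`mode = "refit"`, the default: the training data
#' are reweighted around the query point and the local problem solved) or
#' copied from the nearest regression point (`mode = "nearest"`). Global
#' methods apply the single coefficient vector. Covariate values are used as
#' given (no measurement-error correction is applied to new rows).
#'
#' @param object a [gwtls()] fit.
#' @param newdata data frame with the model covariates and, for local
#'   methods, the coordinate columns used at fit time.
#' @param mode `"refit"` or `"nearest"` (local methods only).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gwtls <- function(object, newdata, mode = c("refit", "nearest"), ...) {
  mode <- match.arg(mode)
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols))
    stop("newdata lacks covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  Anew <- cbind(as.matrix(newdata[object$features]), 1)

  if (object$method %in% c("ols", "wtls"))
    return(drop(Anew %*% object$fit$coefficients))

  cn <- object$coord_names
  if (!all(cn %in% names(newdata)))
    stop("newdata lacks coordinate column(s): ",
         paste(setdiff(cn, names(newdata)), collapse = ", "))
  pts <- cbind(newdata[[cn[1]]], newdata[[cn[2]]])

  if (mode == "nearest") {
    tr_pts <- object$fit$points
    idx <- apply(pts, 1, function(p)
      which.min((tr_pts[, 1] - p[1])^2 + (tr_pts[, 2] - p[2])^2))
    cf <- object$fit$coefficients[idx, , drop = FALSE]
  } else {
    refit <- if (object$method == "gwr")
      gwr_fit(object$system, bandwidth = object$bandwidth,
              regression_points = pts)
    else
      gwtlsr_fit(object$system, bandwidth = object$bandwidth,
                 tol = object$tol, max_iter = object$max_iter,
                 regression_points = pts)
    cf <- refit$coefficients
  }
  rowSums(Anew * cf)
}

#' Diagnostic plots for a fitted spatial LUR model
#'
#' Two base-graphics panels: observed vs estimated response with the 1:1
#' line, and a residual bubble map over the site coordinates (circle area
#' proportional to |residual|, filled for positive residuals).
#'
#' @param x a [gwtls()] fit.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.gwtls <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  y <- x$system$y; yhat <- fitted(x)
  plot(y, yhat, xlab = "observed", ylab = "estimated",
       main = toupper(x$method), ...)
  graphics::abline(0, 1, lty = 2)
  r <- residuals(x)
  cex <- 0.5 + 2.5 * sqrt(abs(r) / max(abs(r)))
  plot(x$system$coords, cex = cex, pch = ifelse(r >= 0, 19, 1),
       xlab = "u (m)", ylab = "v (m)", main = "residuals", asp = 1)
  invisible(x)
}
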