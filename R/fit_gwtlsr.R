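#' Geographically weighted total least squares regression
#'
#' The hybrid estimator at the core of this package: at every regression
#' point the weighted total least squares problem is solved with the Gaussian
#' kernel supplying the response covariance, \eqn{Q_y = W(u_i, v_i)^{-1}},
#' while the covariate measurement variances supply \eqn{Q_A}. Distant
#' observations thus get large response variance (little influence), and
#' noisy covariates are corrected for their errors-in-variables attenuation —
#' spatial nonstationarity and covariate inaccuracy are handled
#' simultaneously.
#'
#' Kernel weights below `1e-12` are clamped to that floor before inversion
#' (an exact zero weight would make \eqn{Q_y} undefined). Per-point
#' non-convergence of the WTLS iteration is collected and reported in a
#' single warning naming the affected locations.
#'
#' @inheritParams gwr_fit
#' @param tol,max_iter convergence controls of the per-point WTLS iteration
#'   (see [wtls_fit()]). `max_iter = 1` gives the one-shot first-iteration
#'   correction instead of the full fixed point.
#' @return object of class `gwtlsr_fit`: `coefficients` (p×n local
#'   coefficients), `points`, `bandwidth`, `locals` (per unique regression
#'   point, the full [wtls_fit()] solution), and — at the data's own
#'   coordinates — `fitted`, `residuals`, `hat_trace`, `rss`. The hat trace
#'   uses the corrected design \eqn{\tilde A = A - \tilde E_A} and the final
#'   combined covariance \eqn{Q_{\tilde y}}.
#' @export
gwtlsr_fit <- function(system, bandwidth, tol = 1e-10, max_iter = 100L,
                       regression_points = NULL) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("bandwidth must be a single positive number")
  A <- system$A; y <- system$y; coords <- system$coords
  at_data <- is.null(regression_points)
  pts <- if (at_data) coords else as.matrix(regression_points)

  key <- paste(pts[, 1], pts[, 2], sep = "\r")
  grp <- match(key, unique(key))
  upts <- pts[!duplicated(key), , drop = FALSE]

  n <- ncol(A)
  coef_u <- matrix(NA_real_, nrow(upts), n)
  locals <- vector("list", nrow(upts))
  hat_diag <- if (at_data) numeric(nrow(A)) else NULL
  bad <- character(0)

  for (g in seq_len(nrow(upts))) {
    w <- weight_matrix(coords, upts[g, ], bandwidth)
    w <- pmax(w, .weight_floor)
    if (sum(w > .weight_floor) < n)
      stop(sprintf(
        "fewer than %d observations carry weight above the floor at location (%.6g, %.6g)",
        n, upts[g, 1], upts[g, 2]))
    fit_g <- withCallingHandlers(
      wtls_fit(system, tol = tol, max_iter = max_iter, qy = 1 / w),
      warning = function(wn) {
        if (grepl("did not converge", conditionMessage(wn))) {
          bad <<- c(bad, sprintf("(%.6g, %.6g)", upts[g, 1], upts[g, 2]))
          invokeRestart("muffleWarning")
        }
      })
    coef_u[g, ] <- fit_g$coefficients
    locals[[g]] <- fit_g
    if (at_data) {
      rows <- which(grp == g)
      At <- A - fit_g$E_A_tilde
      Minv <- solve(crossprod(At, At / fit_g$qy_tilde))
      hat_diag[rows] <- rowSums((At[rows, , drop = FALSE] %*% Minv) *
                                  At[rows, , drop = FALSE]) /
        fit_g$qy_tilde[rows]
    }
  }
  if (length(bad))
    warning("WTLS iteration did not converge at ", length(bad),
            " regression point(s): ", paste(bad, collapse = ", "))

  coefficients <- coef_u[grp, , drop = FALSE]
  colnames(coefficients) <- colnames(A)

  out <- list(coefficients = coefficients, points = pts,
              bandwidth = bandwidth, locals = locals,
              converged = vapply(locals, function(l) isTRUE(l$converged),
                                 TRUE)[grp])
  if (at_data) {
    fitted <- rowSums(A * coefficients)
    out$fitted <- fitted
    out$residuals <- y - fitted
    out$hat_trace <- sum(hat_diag)
    out$rss <- sum(out$residuals^2)
  }
  structure(out, class = "gwtlsr_fit")
}
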