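#' Geographically weighted regression on a design system
#'
#' Local linear regression: at every regression point a weighted least squares
#' problem is solved, with Gaussian distance-decay weights
#' \eqn{W_k(u,v) = \exp(-d_k^2/b^2)} giving nearby observations more
#' influence. The result is a spatially varying coefficient vector
#' \eqn{\hat{x}(u_i, v_i) = (A^T W A)^{-1} A^T W y}.
#'
#' Observations sharing exact coordinates share a local fit (the weighted
#' system is identical), so repeated station locations cost one solve each.
#'
#' @param system a [design_system()].
#' @param bandwidth Gaussian kernel bandwidth in meters, `> 0`.
#' @param regression_points optional p×2 matrix of locations at which to
#'   estimate local coefficients; defaults to the system's own coordinates,
#'   in which case fitted values, residuals and the hat-matrix trace are
#'   populated.
#' @return object of class `gwr_fit`: `coefficients` (p×n matrix of local
#'   coefficients, one row per regression point, intercept last), `points`,
#'   `bandwidth`, and — when fitting at the data's own coordinates —
#'   `fitted`, `residuals`, `hat_trace` (tr(S), the effective number of
#'   parameters), `rss`.
#' @export
gwr_fit <- function(system, bandwidth, regression_points = NULL) {
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
  hat_diag <- if (at_data) numeric(nrow(A)) else NULL

  for (g in seq_len(nrow(upts))) {
    w <- weight_matrix(coords, upts[g, ], bandwidth)
    if (sum(w > .weight_floor) < n)
      stop(sprintf(
        "fewer than %d observations carry weight above the floor at location (%.6g, %.6g)",
        n, upts[g, 1], upts[g, 2]))
    loc <- wls_local(A, y, w, where = upts[g, ])
    coef_u[g, ] <- loc$coefficients
    if (at_data) {
      rows <- which(grp == g)
      # r_i = A(i,:) (A'WA)^-1 A'W ; diagonal entry uses w at the point itself
      hat_diag[rows] <- rowSums((A[rows, , drop = FALSE] %*% loc$Minv) *
                                  A[rows, , drop = FALSE]) * w[rows]
    }
  }
  coefficients <- coef_u[grp, , drop = FALSE]
  colnames(coefficients) <- colnames(A)

  out <- list(coefficients = coefficients, points = pts,
              bandwidth = bandwidth)
  if (at_data) {
    fitted <- rowSums(A * coefficients)
    out$fitted <- fitted
    out$residuals <- y - fitted
    out$hat_trace <- sum(hat_diag)
    out$rss <- sum(out$residuals^2)
  }
  structure(out, class = "gwr_fit")
}
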