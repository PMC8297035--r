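#' Ordinary least squares on a design system
#'
#' Global linear fit with equal unit weights: minimizes the sum of squared
#' response errors, treating the covariates as exact. Coefficients solve the
#' normal equations \eqn{\hat{x} = (A^T A)^{-1} A^T y}.
#'
#' @param system a [design_system()].
#' @return list of class `ols_fit` with `coefficients` (named, intercept
#'   last), `fitted`, `residuals`, `hat_trace` (= number of columns of A),
#'   and `rss`.
#' @export
ols_fit <- function(system) {
  A <- system$A; y <- system$y
  check_full_rank(A)
  xhat <- drop(solve(crossprod(A), crossprod(A, y)))
  fitted <- drop(A %*% xhat)
  structure(
    list(coefficients = xhat, fitted = fitted, residuals = y - fitted,
         hat_trace = ncol(A), rss = sum((y - fitted)^2)),
    class = "ols_fit"
  )
}

# weighted least squares at one regression point: solves the local normal
# equations A' W A x = A' W y and returns the local hat diagonal contribution
wls_local <- function(A, y, w, where = NULL) {
  M <- crossprod(A, A * w)
  xhat <- tryCatch(
    drop(solve(M, crossprod(A, y * w))),
    error = function(e) {
      loc <- if (is.null(where)) "" else
        sprintf(" at location (%.6g, %.6g)", where[1], where[2])
      stop("weighted system is numerically singular", loc,
           " (too little effective weight for ", ncol(A), " unknowns)",
           call. = FALSE)
    }
  )
  list(coefficients = xhat, Minv = solve(M))
}
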