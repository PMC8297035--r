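#' Weighted total least squares on a design system
#'
#' Errors-in-variables fit: both the response and the covariates are treated
#' as noisy observations, with known per-cell variances. The estimator
#' minimizes the joint quadratic form
#' \deqn{\phi = e_y^T Q_y^{-1} e_y + e_A^T Q_A^{-1} e_A}
#' subject to \eqn{y = (A - E_A)x + e_y}, solved with Lagrange multipliers and
#' an iterative fixed-point scheme initialized at the OLS solution:
#' \enumerate{
#'   \item \eqn{Q_{\tilde y} = Q_y + (x^T \otimes I_m) Q_A (x \otimes I_m)}
#'   \item \eqn{\hat\lambda = Q_{\tilde y}^{-1} (y - A\hat{x})}
#'   \item \eqn{\tilde e_A = -Q_A (\hat{x} \otimes I_m) \hat\lambda}
#'   \item \eqn{\hat{x} = (\tilde A^T Q_{\tilde y}^{-1} \tilde A)^{-1}
#'     \tilde A^T Q_{\tilde y}^{-1} \tilde y} with
#'     \eqn{\tilde A = A - \tilde E_A}, \eqn{\tilde y = y - \tilde E_A \hat{x}}.
#' }
#' Since the measurement variances are per-cell, \eqn{Q_A} is diagonal and the
#' whole cycle reduces to elementwise operations plus one n×n solve per
#' iteration. Because the intercept column carries zero variance, its
#' estimated design error is exactly zero in every iteration.
#'
#' Convergence is declared when
#' \eqn{\|\hat{x}_t - \hat{x}_{t-1}\|_\infty / \max(1, \|\hat{x}_t\|_\infty)}
#' drops below `tol`. If the iteration exhausts `max_iter`, the result is
#' returned with `converged = FALSE` and a warning. The returned solution is
#' never worse (in the profiled objective) than the OLS starting point: if the
#' final iterate is, the best iterate seen is returned instead (recorded in
#' `diagnostics`).
#'
#' @param system a [design_system()] with `qa_variances` and `qy` populated.
#' @param tol relative convergence tolerance on the coefficient vector.
#' @param max_iter maximum number of update cycles.
#' @param qy optional override of the system's response variances (used by the
#'   geographically weighted variant, where \eqn{Q_y = W^{-1}}).
#' @return object of class `wtls_fit`: `coefficients` (\eqn{\hat{x}}),
#'   `E_A_tilde` (m×n estimated design errors), `lambda` (Lagrange
#'   multipliers), `qy_tilde` (diagonal of the combined covariance),
#'   `ey_tilde` (estimated response errors), `objective` (value of
#'   \eqn{\phi} at the solution), `fitted`, `residuals` (\eqn{y - A\hat{x}},
#'   raw design), `iterations`, `converged`, `diagnostics`.
#' @export
wtls_fit <- function(system, tol = 1e-10, max_iter = 100L, qy = NULL) {
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  A <- system$A; y <- system$y; V <- system$qa_variances
  if (is.null(qy)) qy <- system$qy
  m <- nrow(A); n <- ncol(A)

  check_full_rank(A)
  x_prev <- drop(solve(crossprod(A), crossprod(A, y)))  # OLS start

  # profiled objective phi(x) = r' Q_ytilde(x)^-1 r with r = y - A x;
  # equal to Eq-(7)'s phi at the constrained stationary errors for that x
  qyt_of <- function(x) qy + drop(V %*% x^2)
  profiled <- function(x) {
    r <- y - drop(A %*% x)
    sum(r^2 / qyt_of(x))
  }

  obj_init <- profiled(x_prev)
  best_x <- x_prev; best_obj <- obj_init
  used_best <- FALSE
  converged <- FALSE
  iter <- 0L
  x <- x_prev
  E <- matrix(0, m, n, dimnames = dimnames(A))
  lambda <- numeric(m)
  qyt <- qyt_of(x)

  while (iter < max_iter) {
    iter <- iter + 1L
    qyt <- qyt_of(x)
    if (any(!is.finite(qyt)) || any(qyt <= 0))
      stop("combined covariance Q_y~ is numerically singular")
    lambda <- (y - drop(A %*% x)) / qyt
    # E_A column k = -delta^2_{.k} * x_k * lambda (diagonal Q_A)
    E <- -V * tcrossprod(lambda, x)
    At <- A - E
    yt <- y - drop(E %*% x)
    x_new <- tryCatch(
      drop(solve(crossprod(At, At / qyt), crossprod(At, yt / qyt))),
      error = function(e)
        stop("combined covariance Q_y~ is numerically singular", call. = FALSE)
    )
    step <- max(abs(x_new - x)) / max(1, max(abs(x_new)))
    x <- x_new
    ob <- profiled(x)
    if (is.finite(ob) && ob < best_obj) { best_obj <- ob; best_x <- x }
    if (step < tol) { converged <- TRUE; break }
  }

  if (!converged)
    warning("WTLS iteration did not converge in ", max_iter, " iterations")

  if (profiled(x) > best_obj + 1e-12 * max(1, best_obj)) {
    x <- best_x
    used_best <- TRUE
  }

  # final consistent errors at the returned x
  qyt <- qyt_of(x)
  lambda <- (y - drop(A %*% x)) / qyt
  E <- -V * tcrossprod(lambda, x)
  ey <- y - drop((A - E) %*% x)          # response errors of y=(A-E_A)x+e_y
  pos <- V > 0
  objective <- sum(ey^2 / qy) + sum(E[pos]^2 / V[pos])
  fitted <- drop(A %*% x)

  structure(
    list(coefficients = x, E_A_tilde = E, lambda = lambda, qy_tilde = qyt,
         ey_tilde = ey, objective = objective, fitted = fitted,
         residuals = y - fitted, iterations = iter, converged = converged,
         diagnostics = list(objective_init = obj_init,
                            returned_best_iterate = used_best)),
    class = "wtls_fit"
  )
}
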