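#' Assemble a regression design system
#'
#' Bundles everything the estimators in this package need: the design matrix
#' with a trailing intercept column, the observation vector, per-cell
#' measurement variances for the covariates, per-observation variances for the
#' response, and projected planar coordinates.
#'
#' The intercept column of ones is appended as the *last* column of the design
#' matrix, and its measurement variance is identically zero (an intercept is
#' not observed, so it carries no error). Covariate variances \eqn{\delta^2_{aik}}
#' form the diagonal of the design covariance \eqn{Q_A} (column-major, intercept
#' block last); response variances form the diagonal of \eqn{Q_y}.
#'
#' @param x numeric matrix or data frame of covariate values, one row per
#'   observation, one column per covariate (no intercept column; it is added).
#' @param y numeric response vector (e.g. PM2.5 concentration in µg/m³).
#' @param coords two-column numeric matrix of projected planar coordinates in
#'   meters (e.g. UTM easting/northing), one row per observation.
#' @param var_x per-cell measurement variances of `x`: a matrix the same shape
#'   as `x`, a vector of per-column variances (recycled down rows), or a single
#'   value. Defaults to 0 (covariates treated as exact).
#' @param var_y per-observation variances of `y`: vector or single value,
#'   default 1 (equal weights).
#'
#' @return An object of class `design_system`: a list with elements `A`
#'   (m×n design matrix, intercept last), `y`, `qa_variances` (m×n, intercept
#'   column zero), `qy` (length m), `coords` (m×2), and `terms` (covariate
#'   names).
#' @examples
#' xy <- cbind(runif(10), runif(10))
#' sys <- design_system(x = cbind(f1 = rnorm(10)), y = rnorm(10), coords = xy)
#' sys$A[, "(Intercept)"]
#' @export
design_system <- function(x, y, coords, var_x = 0, var_y = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  m <- length(y)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  if (nrow(x) != m) stop("x and y disagree on the number of observations")
  if (nrow(coords) != m || ncol(coords) != 2)
    stop("coords must be an m x 2 matrix matching y")
  if (anyNA(x) || anyNA(y) || anyNA(coords))
    stop("design system inputs must not contain missing values")

  k <- ncol(x)
  vx <- var_x
  if (is.matrix(vx)) {
    if (!all(dim(vx) == dim(x))) stop("var_x matrix must match the shape of x")
  } else if (length(vx) %in% c(1L, k)) {
    vx <- matrix(rep(as.numeric(vx), each = m), nrow = m, ncol = k)
  } else {
    stop("var_x must be a matrix like x, one value per covariate, or a scalar")
  }
  vx <- as.matrix(vx)
  if (any(vx < 0)) stop("covariate measurement variances must be >= 0")

  qy <- rep_len(as.numeric(var_y), m)
  if (any(qy <= 0)) stop("response variances must be > 0")

  A <- cbind(x, `(Intercept)` = 1)
  qa <- cbind(vx, `(Intercept)` = 0)
  colnames(qa) <- colnames(A)
  n <- ncol(A)
  if (m <= n)
    stop("observations must outnumber unknowns (m = ", m, ", n = ", n, ")")

  structure(
    list(A = A, y = y, qa_variances = qa, qy = qy, coords = coords,
         terms = colnames(x)),
    class = "design_system"
  )
}

#' @export
print.design_system <- function(x, ...) {
  cat("Design system: m =", nrow(x$A), "observations, n =", ncol(x$A),
      "unknowns\n")
  cat("Covariates:", paste(x$terms, collapse = ", "), "\n")
  eiv <- any(x$qa_variances > 0)
  cat("Covariate measurement error:", if (eiv) "present" else "none (exact)",
      "\n")
  invisible(x)
}

#' Build a design system from a station table
#'
#' Convenience wrapper mapping the delimited station-table layout
#' (`station_id`, `u`, `v`, `y`, features, `<feature>__var` columns) onto
#' [design_system()].
#'
#' @param data data frame in station-table layout (see [read_station_table()]).
#' @param features character vector of feature column names; default all
#'   non-reserved, non-`__var` columns.
#' @param var_default global variance used for features lacking a `__var`
#'   column; `NULL` (default) makes a missing `__var` column an error.
#' @return A `design_system`.
#' @export
as_design_system <- function(data, features = NULL, var_default = NULL) {
  reserved <- c("station_id", "u", "v", "y", "date")
  if (is.null(features)) {
    features <- setdiff(names(data), reserved)
    features <- features[!grepl("__var$", features)]
  }
  missing_cols <- setdiff(c("u", "v", "y", features), names(data))
  if (length(missing_cols))
    stop("station table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  vx <- matrix(0, nrow(data), length(features),
               dimnames = list(NULL, features))
  for (f in features) {
    vc <- paste0(f, "__var")
    if (vc %in% names(data)) {
      vx[, f] <- data[[vc]]
    } else if (!is.null(var_default)) {
      vx[, f] <- var_default
    } else {
      stop("no '", vc, "' variance column for feature '", f,
           "' and no var_default given")
    }
  }
  design_system(x = as.matrix(data[features]), y = data$y,
                coords = cbind(u = data$u, v = data$v), var_x = vx)
}

# rank check shared by the global fitters; names the offending columns
check_full_rank <- function(A) {
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    bad <- colnames(A)[qrA$pivot[(qrA$rank + 1L):ncol(A)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
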