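#' Fixed Gaussian kernel weight
#'
#' Distance-decay weight `exp(-d^2 / b^2)` used by the geographically weighted
#' estimators: 1 at the regression point itself, strictly decreasing with
#' distance, with the bandwidth `b` setting the decay scale in meters.
#'
#' @param d distance(s) in meters, `>= 0`.
#' @param b bandwidth in meters, `> 0`.
#' @return weights in `(0, 1]`, same length as `d`.
#' @examples
#' gaussian_weight(c(0, 500, 1000), b = 500)
#' @export
gaussian_weight <- function(d, b) {
  if (!is.numeric(b) || length(b) != 1L || b <= 0)
    stop("bandwidth b must be a single positive number")
  if (any(d < 0)) stop("distances must be >= 0")
  exp(-(d / b)^2)
}

#' Diagonal spatial weight matrix at a target location
#'
#' Evaluates the Gaussian kernel at the Euclidean distance from every site to
#' the target location, returning the diagonal of the GWR weight matrix
#' W(u, v).
#'
#' @param coords m×2 matrix of projected site coordinates (meters).
#' @param target length-2 numeric, the regression point (u, v).
#' @param b bandwidth in meters.
#' @return numeric vector of length m: the diagonal entries of W(u, v).
#' @export
weight_matrix <- function(coords, target, b) {
  coords <- as.matrix(coords)
  d <- sqrt((coords[, 1] - target[1])^2 + (coords[, 2] - target[2])^2)
  gaussian_weight(d, b)
}

# weights below this are clamped before inversion into Q_y; Gaussian weights
# underflow at large distance and Q_y = W^-1 would be undefined at exact zero
.weight_floor <- 1e-12

#' Select the kernel bandwidth by AICc
#'
#' Minimizes the corrected Akaike information criterion of a GWR or GWTLSR fit
#' as a function of bandwidth, using golden-section search on log-bandwidth.
#' The search is deterministic: the same system and bounds always return the
#' same bandwidth. Exact ties between probe points are broken toward the
#' smaller bandwidth (noted via `message()`).
#'
#' @param system a [design_system()].
#' @param model `"gwr"` or `"gwtlsr"`: which estimator's AICc profile to
#'   minimize.
#' @param lower,upper search bounds in meters; default 0.1× and 10× the
#'   maximum pairwise site distance.
#' @param search_tol relative tolerance of the golden-section search on log
#'   scale.
#' @param ... passed to the underlying fitter (e.g. `tol`, `max_iter` for
#'   GWTLSR).
#' @return list with `bandwidth` (the minimizer), `aicc` (its criterion
#'   value), and `profile` (data frame of every bandwidth/AICc pair
#'   evaluated).
#' @export
select_bandwidth <- function(system, model = c("gwr", "gwtlsr"),
                             lower = NULL, upper = NULL, search_tol = 1e-3,
                             ...) {
  model <- match.arg(model)
  dmax <- max(stats::dist(system$coords))
  if (dmax <= 0) stop("all sites are coincident; bandwidth is undefined")
  if (is.null(lower)) lower <- 0.1 * dmax
  if (is.null(upper)) upper <- 10 * dmax
  if (!(0 < lower && lower < upper)) stop("need 0 < lower < upper")

  evals <- list()
  objective <- function(logb) {
    b <- exp(logb)
    val <- tryCatch({
      fit <- if (model == "gwr") gwr_fit(system, bandwidth = b)
             else gwtlsr_fit(system, bandwidth = b, ...)
      aicc(system, fit)
    }, error = function(e) Inf)
    evals[[length(evals) + 1L]] <<- c(bandwidth = b, aicc = val)
    val
  }

  # golden-section on log-bandwidth; ties go to the smaller bandwidth
  phi <- (sqrt(5) - 1) / 2
  lo <- log(lower); hi <- log(upper)
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- objective(x1); f2 <- objective(x2)
  tied <- FALSE
  while ((hi - lo) > search_tol * max(1, abs(hi))) {
    if (f1 == f2) tied <- TRUE
    if (f1 <= f2) {          # keep the lower interval on ties
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- objective(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- objective(x2)
    }
  }
  if (tied)
    message("flat AICc profile encountered; tie broken toward the smaller bandwidth")
  b_hat <- exp((lo + hi) / 2)
  f_hat <- objective(log(b_hat))
  if (!is.finite(f_hat) && !any(is.finite(vapply(evals, `[[`, 0, "aicc"))))
    stop("no admissible bandwidth in the search bounds (all fits singular)")
  profile <- as.data.frame(do.call(rbind, evals))
  profile <- profile[order(profile$bandwidth), , drop = FALSE]
  rownames(profile) <- NULL
  list(bandwidth = b_hat, aicc = f_hat, profile = profile)
}
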