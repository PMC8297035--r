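# Independent oracles and small fixture builders. Everything here avoids the
# package's own solution paths: OLS via qr.solve, WTLS via direct numerical
# minimization of the profiled objective, hat traces via the full matrix.

# small random errors-in-variables system (m x n with intercept last)
random_system <- function(seed, m = 6, k = 1, eiv = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(m * k, mean = 2, sd = 1.5), m, k,
              dimnames = list(NULL, paste0("f", seq_len(k))))
  beta <- c(rnorm(k), rnorm(1, 3))
  y <- drop(cbind(x, 1) %*% beta) + rnorm(m, sd = 0.5)
  design_system(
    x = x, y = y, coords = cbind(runif(m, 0, 1000), runif(m, 0, 1000)),
    var_x = if (eiv) matrix(runif(m * k, 0.05, 0.5), m, k) else 0,
    var_y = runif(m, 0.5, 1.5))
}

# profiled WTLS objective phi(x) = (y - Ax)' [Q_y + sum_k x_k^2 diag(d2_k)]^-1 (y - Ax)
profiled_objective <- function(system, x, qy = system$qy) {
  r <- system$y - drop(system$A %*% x)
  qyt <- qy + drop(system$qa_variances %*% x^2)
  sum(r^2 / qyt)
}

# brute-force WTLS: dense grid around the QR-based OLS solution, then
# Nelder-Mead refinement (restarted) on the profiled objective
wtls_oracle <- function(system, grid_half_width = 2, grid_n = 21) {
  x0 <- qr.solve(system$A, system$y)
  n <- length(x0)
  f <- function(x) profiled_objective(system, x)
  grids <- lapply(seq_len(n), function(j)
    seq(x0[j] - grid_half_width, x0[j] + grid_half_width,
        length.out = grid_n))
  grid <- as.matrix(expand.grid(grids))
  vals <- apply(grid, 1, f)
  best <- grid[which.min(vals), ]
  for (i in 1:3) {
    opt <- stats::optim(best, f, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    best <- opt$par
  }
  list(x = best, objective = opt$value)
}

# two well-separated site clusters, each exactly on its own line
two_cluster_data <- function() {
  set.seed(99)
  x1 <- c(0, 1, 2, 3); x2 <- c(0, 1, 2, 3)
  y1 <- 1 + 2 * x1          # cluster A: intercept 1, slope 2
  y2 <- 5 - 1 * x2          # cluster B: intercept 5, slope -1
  design_system(
    x = cbind(f = c(x1, x2)), y = c(y1, y2),
    coords = rbind(cbind(runif(4, 0, 50), runif(4, 0, 50)),
                   cbind(1e5 + runif(4, 0, 50), 1e5 + runif(4, 0, 50))))
}

# full hat matrix of a weighted global least squares fit
hat_trace_oracle <- function(A, w = rep(1, nrow(A))) {
  S <- A %*% solve(crossprod(A, A * w), t(A * w))
  sum(diag(S))
}

# all permutations of 1..n as rows (n small)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# Moran's I by direct formula evaluation (row-standardized weights supplied)
morans_i_direct <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}
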