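# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package internals.

# Brute-force power iteration for the dominant eigenpair of a non-negative
# primitive matrix, normalised by the L1 norm.
oracle_power_iteration <- function(A, tol = 1e-14, maxit = 1e6) {
  x <- rep(1, nrow(A)) / nrow(A)
  lambda <- NA_real_
  for (i in seq_len(maxit)) {
    y <- as.vector(A %*% x)
    lambda_new <- sum(abs(y))
    y <- y / lambda_new
    if (max(abs(y - x)) < tol) return(list(lambda = lambda_new, w = y))
    x <- y
    lambda <- lambda_new
  }
  list(lambda = lambda, w = x)
}

# Analytic elasticity of one matrix element from left/right eigenvectors,
# computed with base eigen() directly (independent of the package helpers).
oracle_elasticity <- function(A, i, j) {
  A <- unclass(A)
  attr(A, "rates") <- NULL
  er <- eigen(A)
  k <- which.max(Re(er$values))
  lambda <- Re(er$values[k])
  w <- Re(er$vectors[, k])
  el <- eigen(t(A))
  kl <- which.max(Re(el$values))
  v <- Re(el$vectors[, kl])
  s <- v[i] * w[j] / sum(v * w)
  s * A[i, j] / lambda
}

# Newton-Raphson maximum likelihood for logistic regression with a full
# Hessian (not IRLS); X includes the intercept column.
oracle_newton_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- as.vector(t(X) %*% (y - p))
    W <- p * (1 - p)
    H <- t(X) %*% (X * W)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Closed-form triangular moments.
oracle_tri_mean <- function(a, m, b) (a + m + b) / 3

# Default study conditions shared across tests.
default_matrix <- function() projection_matrix(vital_rates())

# The 13 printed yearly proportions of reproductively active females
# (1996-2008) from the reference study system.
yearly_repro_proportions <- c(
  0.818, 1.000, 0.846, 0.957, 0.846, 1.000, 1.000,
  0.900, 0.944, 0.813, 0.805, 0.727, 0.778
)
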