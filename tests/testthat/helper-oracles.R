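# Independent oracles used across the suite: brute-force enumeration /
# quadrature over product grids, and central finite differences.

# integration grid for one margin: discrete support with unit weights,
# or a fine trapezoid grid for the Gaussian margin
margin_nodes <- function(margin, mu, n_cont = 801L) {
  if (margin$family == "gaussian") {
    s <- sqrt(margin$nuisance[["tau2"]])
    x <- seq(mu - 10 * s, mu + 10 * s, length.out = n_cont)
    w <- rep(x[2L] - x[1L], n_cont)
    w[c(1L, n_cont)] <- w[1L] / 2
    list(x = x, w = w)
  } else if (margin$family == "bernoulli") {
    list(x = c(0, 1), w = c(1, 1))
  } else {
    M <- apxcopula:::margin_upper_quantile(margin, mu) + 5L
    list(x = 0:M, w = rep(1, M + 1L))
  }
}

# full product grid over an ac_dist / ac_tilted: matrix of points,
# vector of quadrature weights
dist_grid <- function(dist, n_cont = 801L) {
  nodes <- lapply(seq_along(dist$mu), function(k)
    margin_nodes(dist$margins[[k]], dist$mu[k], n_cont))
  pts <- expand.grid(lapply(nodes, `[[`, "x"))
  wts <- expand.grid(lapply(nodes, `[[`, "w"))
  list(y = as.matrix(pts), w = apply(as.matrix(wts), 1L, prod))
}

# oracle integral of the density (should be 1)
oracle_mass <- function(dist, n_cont = 801L) {
  g <- dist_grid(dist, n_cont)
  sum(dac(g$y, dist) * g$w)
}

# oracle mean / covariance by enumeration or quadrature
oracle_moments <- function(dist, n_cont = 801L) {
  g <- dist_grid(dist, n_cont)
  p <- dac(g$y, dist) * g$w
  m <- colSums(g$y * p)
  ctr <- sweep(g$y, 2L, m)
  list(mean = m, cov = crossprod(ctr, ctr * p))
}

fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

fd_jac <- function(f, x, h = 1e-6) {
  cols <- lapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  })
  do.call(cbind, cols)
}

# small simulation-I fixture shared by estimation tests
make_pois_units <- function(n = 60, d = 4, theta = 0.15, p = 2,
                            seed = 1) {
  sim_longitudinal("I", n = n, d = d, family = "poisson",
                   theta = theta, p = p, seed = seed)$units
}

`%||%` <- function(a, b) if (is.null(a)) b else a
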