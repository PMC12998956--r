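#' Sequential stage density for sampling
#'
#' Random vectors from an [ac_dist()] are generated one component at a
#' time: the first component from its marginal, each later component
#' `i` from its conditional given the realized standardized residuals
#' of components `1..i-1`.  Every stage density is univariate and of
#' the tilted form `f_i(y)[b0 + b1 r + b2 r^2]` with normalizer
#' `d_[i-1] = 1 + r'_[i-1] Gamma_[i-1] r_[i-1]/2 + sum_{j>=i}
#' gamma_jj / 2`.
#'
#' @param dist an [ac_dist()] object.
#' @param i component index, `1 <= i <= d`.
#' @param r_prev realized standardized residuals of components
#'   `1..i-1` (length `i-1`; empty for `i = 1`).
#' @return an `"ac_tilted"` univariate density, evaluable with [dac()].
#' @export
ac_stage_density <- function(dist, i, r_prev = numeric(0)) {
  G <- dist$Gamma; d <- length(dist$mu)
  stopifnot(i >= 1L, i <= d, length(r_prev) == i - 1L)
  prev <- seq_len(i - 1L)
  quad_prev <- if (i > 1L)
    drop(crossprod(r_prev, G[prev, prev, drop = FALSE] %*% r_prev)) else 0
  d_prev <- 1 + quad_prev / 2 + sum(diag(G)[i:d]) / 2
  b1 <- if (i > 1L) sum(r_prev * G[prev, i]) else 0
  ac_tilted(dist$margins[i], dist$mu[i],
            a = d_prev - G[i, i] / 2, b = b1,
            G = matrix(G[i, i], 1L, 1L))
}

#' Inverse-method draw from a discrete pmf, mode first
#'
#' Inversion over a reordering of the probabilities that puts the bulk
#' of the mass first: with `k = floor(nu)`, the sequence visits
#' `p_k, p_{k+1}, p_{k-1}, p_{k+2}, p_{k-2}, ...`.  The cumulative
#' partition of `[0,1)` is over the reordered sequence, so most draws
#' terminate after a few comparisons; the resulting distribution is
#' identical to natural-order inversion.
#'
#' @param prob probability vector (normalized internally).
#' @param nu mean hint; the reordering starts at `floor(nu)`.
#' @param u uniform deviate in `[0, 1)`.
#' @param support integer support values aligned with `prob`
#'   (default `0:(length(prob)-1)`).
#' @return one support value.
#' @export
ac_draw_discrete <- function(prob, nu, u, support = seq_along(prob) - 1L) {
  stopifnot(length(prob) == length(support), u >= 0, u < 1)
  prob <- prob / sum(prob)
  k <- which.min(abs(support - floor(nu)))   # index of the hinted mode
  n <- length(prob)
  lo <- k; hi <- k; ord <- k
  while (lo > 1L || hi < n) {                # k, k+1, k-1, k+2, k-2, ...
    if (hi < n) { hi <- hi + 1L; ord <- c(ord, hi) }
    if (lo > 1L) { lo <- lo - 1L; ord <- c(ord, lo) }
  }
  cum <- cumsum(prob[ord])
  support[ord[which(u < cum)[1L]]]
}

#' Inverse-transform draw from a Gaussian stage density
#'
#' For a Gaussian base the stage CDF has the closed form
#' `F(z) = [b0 Phi(z) - b1 phi(z) + b2 (Phi(z) - z phi(z))] / (b0 + b2)`
#' in the standardized residual `z`, using the partial moments
#' `int_{-inf}^x y phi(y) dy = -phi(x)` and
#' `int_{-inf}^x y^2 phi(y) dy = Phi(x) - x phi(x)`.  `F(z) = u` is
#' solved by safeguarded Newton iteration (bisection fallback on a
#' bracket from extreme base quantiles).
#'
#' @param stage a univariate `"ac_tilted"` density with a Gaussian
#'   margin, e.g. from [ac_stage_density()].
#' @param u uniform deviate(s) in `(0, 1)`.
#' @return numeric draw(s) on the response scale.
#' @export
ac_draw_continuous <- function(stage, u) {
  m <- stage$margins[[1L]]
  if (m$family != "gaussian")
    stop("closed-form continuous stage sampling is implemented for the ",
         "Gaussian base only (family '", m$family, "' requested)")
  b0 <- stage$a; b1 <- stage$b; b2 <- stage$G[1L, 1L] / 2
  z <- .gauss_stage_solve(rep_len(b0, length(u)), rep_len(b1, length(u)),
                          rep_len(b2, length(u)), u)
  stage$mu[1L] + sqrt(m$nuisance[["tau2"]]) * z
}

# standardized-scale CDF of phi(z)[b0 + b1 z + b2 z^2] / (b0 + b2)
.gauss_stage_cdf <- function(z, b0, b1, b2) {
  (b0 * stats::pnorm(z) - b1 * stats::dnorm(z) +
     b2 * (stats::pnorm(z) - z * stats::dnorm(z))) / (b0 + b2)
}

# vectorized safeguarded Newton for F(z) = u
.gauss_stage_solve <- function(b0, b1, b2, u) {
  lo <- rep_len(stats::qnorm(1e-13), length(u))
  hi <- rep_len(stats::qnorm(1 - 1e-13), length(u))
  z <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  Z <- b0 + b2
  for (it in 1:100) {
    f <- .gauss_stage_cdf(z, b0, b1, b2) - u
    lo[f < 0] <- z[f < 0]; hi[f >= 0] <- z[f >= 0]
    df <- stats::dnorm(z) * (b0 + b1 * z + b2 * z^2) / Z
    step <- f / pmax(df, 1e-300)
    z_new <- z - step
    bad <- !is.finite(z_new) | z_new <= lo | z_new >= hi
    z_new[bad] <- (lo[bad] + hi[bad]) / 2      # bisection safeguard
    if (max(abs(z_new - z)) < 1e-12) { z <- z_new; break }
    z <- z_new
  }
  z
}

# pmf of a univariate discrete stage on 0..M (tilt clamped at 0);
# widens the truncation bound once if mass is not covered
.stage_pmf <- function(margin, mu, b0, b1, b2, extra = 10L) {
  if (margin$family == "bernoulli") {
    k <- c(0, 1)
  } else {
    M <- margin_upper_quantile(margin, mu, 1 - 1e-10) + extra
    k <- 0:M
  }
  s <- sqrt(margin_moments(margin, mu)$var)
  r <- (k - mu) / s
  p <- exp(margin_logpdf(margin, k, mu)) * pmax(b0 + b1 * r + b2 * r^2, 0)
  Z <- b0 + b2
  if (margin$family != "bernoulli" && sum(p) / Z < 1 - 1e-8) {
    if (extra > 10L)
      stop("discrete stage mass not reachable within truncation bound")
    return(.stage_pmf(margin, mu, b0, b1, b2,
                      extra = extra + 10L + as.integer(2 * mu)))
  }
  list(support = k, prob = p / sum(p))
}

#' Random vectors from an approximate-copula distribution
#'
#' Draws `n` i.i.d. rows by sequential conditional sampling: the first
#' component from its marginal stage density, each subsequent component
#' from its conditional given the realized residuals.  Discrete stages
#' use inverse sampling over a truncated support; Gaussian stages use
#' the closed-form CDF inversion of [ac_draw_continuous()].  The stream
#' is a deterministic function of R's RNG state (use `set.seed()`).
#'
#' @param n number of draws.
#' @param dist an [ac_dist()] object.
#' @return an `n x d` matrix of draws.
#' @examples
#' set.seed(1)
#' dist <- ac_dist(ac_margin("poisson"), mu = c(2, 3),
#'                 Gamma = matrix(c(.1, .08, .08, .1), 2))
#' colMeans(rac(2000, dist))
#' @export
rac <- function(n, dist) {
  d <- length(dist$mu)
  Mu <- matrix(dist$mu, n, d, byrow = TRUE)
  .sample_tilted_matrix(dist$margins, Mu, dist$Gamma)
}

# batched sampler: margins per column, mean matrix Mu (n x d), shared
# Gamma.  Vectorizes each stage across the n units.
.sample_tilted_matrix <- function(margins, Mu, Gamma) {
  n <- nrow(Mu); d <- ncol(Mu)
  Y <- matrix(0, n, d); R <- matrix(0, n, d)
  dg <- diag(Gamma)
  quad_prev <- numeric(n)
  for (i in seq_len(d)) {
    m <- margins[[i]]
    mu <- Mu[, i]
    s <- sqrt(margin_moments(m, mu)$var)
    d_prev <- 1 + quad_prev / 2 + sum(dg[i:d]) / 2
    b1 <- if (i > 1L)
      drop(R[, seq_len(i - 1L), drop = FALSE] %*% Gamma[seq_len(i - 1L), i])
    else numeric(n)
    b0 <- d_prev - dg[i] / 2
    b2 <- dg[i] / 2
    u <- stats::runif(n)
    if (m$family == "gaussian") {
      z <- .gauss_stage_solve(b0, b1, rep_len(b2, n), u)
      Y[, i] <- mu + s * z
    } else {
      Y[, i] <- .draw_discrete_batch(m, mu, s, b0, b1, b2, u)
    }
    R[, i] <- (Y[, i] - mu) / s
    # update r'_[i] Gamma_[i] r_[i] incrementally
    quad_prev <- quad_prev + 2 * b1 * R[, i] + dg[i] * R[, i]^2
  }
  Y
}

# vectorized discrete stage draw for n units sharing a margin family
.draw_discrete_batch <- function(margin, mu, s, b0, b1, b2, u,
                                 extra = 10L) {
  n <- length(mu)
  if (margin$family == "bernoulli") {
    k <- c(0, 1)
  } else {
    M <- margin_upper_quantile(margin, mu, 1 - 1e-10) + extra
    k <- 0:M
  }
  nk <- length(k)
  K <- matrix(k, n, nk, byrow = TRUE)
  F_ <- matrix(exp(margin_logpdf(margin, rep(k, each = n),
                                 rep(mu, times = nk))), n, nk)
  Rk <- (K - mu) / s
  P <- F_ * pmax(b0 + b1 * Rk + b2 * Rk^2, 0)
  tot <- rowSums(P)
  if (margin$family != "bernoulli") {
    cover <- tot / (b0 + b2)
    if (min(cover) < 1 - 1e-8) {
      if (extra > 10L)
        stop("discrete stage mass not reachable within truncation bound")
      return(.draw_discrete_batch(margin, mu, s, b0, b1, b2, u,
                                  extra = extra + 10L +
                                    as.integer(2 * max(mu))))
    }
  }
  C <- P %*% upper.tri(matrix(0, nk, nk), diag = TRUE)  # row cumsums
  k[rowSums(C < u * tot) + 1L]
}
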