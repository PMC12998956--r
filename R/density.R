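#' Approximate-copula joint distribution
#'
#' Builds the joint distribution of a `d`-vector whose density is the
#' product of independent base margins tilted by a quadratic form in
#' standardized residuals,
#' \deqn{g(y) = c^{-1} \prod_k f_k(y_k)\,
#'       [1 + \tfrac12 r' \Gamma r],\qquad c = 1 + \tfrac12 tr(\Gamma),}
#' where `r_k = (y_k - mu_k)/sigma_k`.  The bracket is bounded below by
#' a positive quantity for PSD `Gamma`, so the log density is always
#' defined.  The family is not a copula: margins are preserved only
#' approximately, with variances inflated by the diagonal of `Gamma`.
#'
#' @param margins a single [ac_margin()] (recycled) or a list of `d`
#'   margins.
#' @param mu numeric vector of `d` base means.
#' @param Gamma `d x d` positive semidefinite tilt matrix.
#' @return an object of class `"ac_dist"` with fields `margins`, `mu`,
#'   `Gamma`, and `norm_const` (`= 1 + tr(Gamma)/2`).
#' @examples
#' dist <- ac_dist(ac_margin("poisson"), mu = c(2, 3), Gamma = 0.2 * diag(2))
#' dac(c(1, 4), dist)
#' ac_moments(dist)$cov
#' @export
ac_dist <- function(margins, mu, Gamma) {
  d <- length(mu)
  if (inherits(margins, "ac_margin")) margins <- rep(list(margins), d)
  stopifnot(length(margins) == d, all(vapply(margins, inherits, TRUE,
                                             "ac_margin")))
  Gamma <- as.matrix(Gamma)
  stopifnot(nrow(Gamma) == d, isSymmetric(Gamma, tol = 1e-8))
  ev <- eigen(Gamma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("Gamma must be positive semidefinite")
  structure(list(margins = margins, mu = as.numeric(mu), Gamma = Gamma,
                 norm_const = 1 + sum(diag(Gamma)) / 2),
            class = "ac_dist")
}

#' @export
print.ac_dist <- function(x, ...) {
  cat("<ac_dist> d =", length(x$mu), "with margins:",
      paste(vapply(x$margins, `[[`, "", "family"), collapse = ", "), "\n")
  cat("  norm const 1 + tr(Gamma)/2 =", format(x$norm_const), "\n")
  invisible(x)
}

# internal generalized tilted density over a subset of components:
#   Z^{-1} prod f_k(y_k) [a + b'r + r' G r / 2],   Z = a + tr(G)/2
# The joint, every marginal, every conditional, and every sequential
# stage density are instances of this form.
ac_tilted <- function(margins, mu, a, b, G) {
  G <- as.matrix(G)
  structure(list(margins = margins, mu = as.numeric(mu), a = a,
                 b = as.numeric(b), G = G, Z = a + sum(diag(G)) / 2),
            class = "ac_tilted")
}

std_resid <- function(margins, mu, y) {
  sd_ <- sqrt(vapply(seq_along(mu), function(k)
    margin_moments(margins[[k]], mu[k])$var, 0))
  (y - mu) / sd_
}

#' Density of a tilted distribution
#'
#' Evaluates the density of an [ac_dist()] object, or of any marginal /
#' conditional / stage object derived from one (class `"ac_tilted"`).
#'
#' @param y numeric vector of length `d`, or a matrix with `d` columns
#'   (one evaluation per row).
#' @param dist an `"ac_dist"` or `"ac_tilted"` object.
#' @param log return the log density?
#' @return numeric vector of (log) density values.
#' @export
dac <- function(y, dist, log = FALSE) {
  if (inherits(dist, "ac_dist"))
    dist <- ac_tilted(dist$margins, dist$mu, a = 1,
                      b = numeric(length(dist$mu)), G = dist$Gamma)
  d <- length(dist$mu)
  y <- if (is.matrix(y)) y else matrix(y, ncol = d)
  stopifnot(ncol(y) == d)
  lf <- 0; R <- matrix(0, nrow(y), d)
  for (k in seq_len(d)) {
    m <- dist$margins[[k]]
    mom <- margin_moments(m, dist$mu[k])
    lf <- lf + margin_logpdf(m, y[, k], dist$mu[k])
    R[, k] <- (y[, k] - dist$mu[k]) / sqrt(mom$var)
  }
  quad <- rowSums((R %*% dist$G) * R)
  lin <- if (any(dist$b != 0)) drop(R %*% dist$b) else 0
  out <- lf + log(dist$a + lin + quad / 2) - log(dist$Z)
  if (log) out else exp(out)
}

#' @export
print.ac_tilted <- function(x, ...) {
  cat("<ac_tilted> density over", length(x$mu),
      "component(s), normalizer Z =", format(x$Z), "\n")
  invisible(x)
}

#' Exact moments of an approximate-copula distribution
#'
#' Mean vector, covariance and correlation matrices computed from the
#' exact (un-truncated) moment expressions of the tilted density:
#' with `c = 1 + tr(Gamma)/2`,
#' `E(Y_k) = mu_k + c^{-1} c_{k3} gamma_kk / (2 sigma_k^2)`,
#' `E[(Y_k - mu_k)^2] = c^{-1}[sigma_k^2 + c_{k4} gamma_kk/(2 sigma_k^2)
#'   + (sigma_k^2/2) sum_{i != k} gamma_ii]`, and
#' `E[(Y_k - mu_k)(Y_l - mu_l)] = c^{-1} sigma_k sigma_l gamma_kl`.
#' With `expand = TRUE` the small-`Gamma` expansions (error of order
#' `||Gamma||^2`) are returned instead, for comparison.
#'
#' @param dist an [ac_dist()] object.
#' @param expand return the truncated small-`Gamma` expressions?
#' @return list with `mean`, `cov`, `corr`.
#' @export
ac_moments <- function(dist, expand = FALSE) {
  d <- length(dist$mu); G <- dist$Gamma
  cc <- dist$norm_const
  mom <- lapply(seq_len(d), function(k)
    margin_moments(dist$margins[[k]], dist$mu[k]))
  s2 <- vapply(mom, `[[`, 0, "var")
  c3 <- vapply(mom, `[[`, 0, "c3")
  c4 <- vapply(mom, `[[`, 0, "c4")
  g <- diag(G)
  if (expand) {
    mean_ <- dist$mu + sqrt(s2) * (c3 / s2^1.5) * g / 2
    cov_ <- sqrt(s2) %o% sqrt(s2) * G
    diag(cov_) <- s2 * (1 + (c4 / s2^2 - 1) * g / 2)
  } else {
    shift <- c3 * g / (2 * s2) / cc
    mean_ <- dist$mu + shift
    m2 <- (sqrt(s2) %o% sqrt(s2)) * G / cc      # E[(Yk-muk)(Yl-mul)], k != l
    diag(m2) <- (s2 + c4 * g / (2 * s2) + s2 * (sum(g) - g) / 2) / cc
    cov_ <- m2 - shift %o% shift
  }
  sd_ <- sqrt(diag(cov_))
  list(mean = mean_, cov = cov_, corr = cov_ / (sd_ %o% sd_))
}

#' Marginal distribution of a subset of components
#'
#' Integrating the joint tilted density over the complement `T` of `S`
#' leaves a density of the same tilted shape over `y_S`: the quadratic
#' coefficient matrix restricts to `Gamma_S` and the constant picks up
#' `tr(Gamma_T)/2`; the normalizer is unchanged.
#'
#' @param dist an [ac_dist()] object.
#' @param S nonempty integer subset of `1:d`.
#' @return an `"ac_tilted"` density over the components in `S`,
#'   evaluable with [dac()].
#' @export
ac_marginal <- function(dist, S) {
  d <- length(dist$mu)
  S <- sort(unique(as.integer(S)))
  if (!length(S) || any(S < 1L | S > d)) stop("S must be a nonempty subset")
  Tc <- setdiff(seq_len(d), S)
  ac_tilted(dist$margins[S], dist$mu[S],
            a = 1 + sum(diag(dist$Gamma)[Tc]) / 2,
            b = numeric(length(S)),
            G = dist$Gamma[S, S, drop = FALSE])
}

#' Conditional distribution given observed components
#'
#' Conditioning the joint density on `Y_T = y_T` again yields a tilted
#' density over the remaining components `S`, with constant
#' `1 + r_T' Gamma_T r_T / 2`, linear term `Gamma_{S,T} r_T`, quadratic
#' matrix `Gamma_S`, and normalizer `1/d_S` where
#' `d_S = [1 + r_T' Gamma_T r_T/2 + tr(Gamma_S)/2]^{-1}`.
#'
#' @param dist an [ac_dist()] object.
#' @param T integer subset of conditioning components.
#' @param y_T observed values for the components in `T` (in the order
#'   of `sort(T)`).
#' @return an `"ac_tilted"` density over the complement of `T`.
#' @export
ac_conditional <- function(dist, T, y_T) {
  d <- length(dist$mu)
  T <- sort(unique(as.integer(T)))
  stopifnot(length(T) == length(y_T), all(T >= 1L & T <= d))
  S <- setdiff(seq_len(d), T)
  if (!length(S)) stop("conditioning on all components leaves nothing")
  rT <- std_resid(dist$margins[T], dist$mu[T], y_T)
  GT <- dist$Gamma[T, T, drop = FALSE]
  ac_tilted(dist$margins[S], dist$mu[S],
            a = 1 + drop(crossprod(rT, GT %*% rT)) / 2,
            b = drop(dist$Gamma[S, T, drop = FALSE] %*% rT),
            G = dist$Gamma[S, S, drop = FALSE])
}
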