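#' Base margin of an approximate-copula model
#'
#' Constructs the marginal base distribution of one response component:
#' the density that the joint model perturbs by a quadratic tilt in
#' standardized residuals.  Each family carries its canonical link and,
#' where needed, a strictly positive nuisance parameter.
#'
#' @param family one of `"gaussian"` (identity link, noise variance
#'   `tau2`), `"bernoulli"` (logit link), `"poisson"` (log link), or
#'   `"nbinom"` (log link, dispersion `r`; variance `mu + mu^2/r`).
#'   `"negative_binomial"` is accepted as an alias for `"nbinom"`.
#' @param tau2 Gaussian noise variance, > 0.  Ignored by other families.
#' @param r negative-binomial dispersion, > 0.  Ignored by other families.
#' @return an object of class `"ac_margin"` with elements `family`,
#'   `link`, and `nuisance` (a named numeric, possibly empty).
#' @examples
#' ac_margin("poisson")
#' ac_margin("nbinom", r = 10)
#' @export
ac_margin <- function(family = c("gaussian", "bernoulli", "poisson",
                                 "nbinom", "negative_binomial"),
                      tau2 = 1, r = 1) {
  family <- match.arg(family)
  if (family == "negative_binomial") family <- "nbinom"
  nuisance <- switch(family,
    gaussian = c(tau2 = as.numeric(tau2)),
    nbinom   = c(r = as.numeric(r)),
    numeric(0))
  if (length(nuisance) && (!is.finite(nuisance) || nuisance <= 0))
    stop("nuisance parameter for family '", family,
         "' must be strictly positive")
  link <- switch(family, gaussian = "identity", bernoulli = "logit",
                 poisson = "log", nbinom = "log")
  structure(list(family = family, link = link, nuisance = nuisance),
            class = "ac_margin")
}

#' @export
print.ac_margin <- function(x, ...) {
  nu <- if (length(x$nuisance))
    paste0(", ", names(x$nuisance), " = ", format(x$nuisance)) else ""
  cat("<ac_margin> ", x$family, " (", x$link, " link", nu, ")\n", sep = "")
  invisible(x)
}

margin_is_discrete <- function(margin)
  margin$family %in% c("bernoulli", "poisson", "nbinom")

check_support <- function(margin, y) {
  bad <- switch(margin$family,
    gaussian  = !is.finite(y),
    bernoulli = !(y %in% c(0, 1)),
    !is.finite(y) | y < 0 | y != round(y))
  if (any(bad))
    stop("response value outside the support of the ", margin$family,
         " family: ", paste(utils::head(y[bad], 3L), collapse = ", "))
  invisible(TRUE)
}

#' Log density of a base margin
#'
#' @param margin an [ac_margin()].
#' @param y response value(s); must lie in the family's support
#'   (0/1 for Bernoulli, nonnegative integers for Poisson and
#'   negative binomial).
#' @param mu mean value(s) in the family's mean space.
#' @return `log f(y; mu, nuisance)`, vectorized over `y`/`mu`.
#' @export
margin_logpdf <- function(margin, y, mu) {
  check_support(margin, y)
  .margin_logpdf(margin, y, mu)
}

# as margin_logpdf, without the support check (inputs already vetted)
.margin_logpdf <- function(margin, y, mu) {
  switch(margin$family,
    gaussian  = stats::dnorm(y, mu, sqrt(margin$nuisance[["tau2"]]),
                             log = TRUE),
    bernoulli = {
      mu <- rep_len(mu, length(y))
      out <- log1p(-mu)
      one <- y == 1
      out[one] <- log(mu[one])
      out
    },
    poisson   = stats::dpois(y, mu, log = TRUE),
    nbinom    = stats::dnbinom(y, size = margin$nuisance[["r"]], mu = mu,
                               log = TRUE))
}

#' Central moments of a base margin
#'
#' Closed-form mean, variance, and third and fourth central moments of
#' the base distribution, together with skewness and kurtosis.  These
#' feed the exact moment formulas of the joint tilted density; the
#' kurtosis always satisfies `kurt >= 1`.
#'
#' @inheritParams margin_logpdf
#' @return a list with `mu`, `var`, `c3`, `c4`, `skew`
#'   (`c3 / var^1.5`) and `kurt` (`c4 / var^2`), each vectorized
#'   over `mu`.
#' @export
margin_moments <- function(margin, mu) {
  out <- switch(margin$family,
    gaussian = {
      t2 <- margin$nuisance[["tau2"]]
      list(var = rep_len(t2, length(mu)), c3 = rep_len(0, length(mu)),
           c4 = rep_len(3 * t2^2, length(mu)))
    },
    bernoulli = {
      v <- mu * (1 - mu)
      list(var = v, c3 = v * (1 - 2 * mu), c4 = v * (1 - 3 * v))
    },
    poisson = list(var = mu, c3 = mu, c4 = mu + 3 * mu^2),
    nbinom = {
      r <- margin$nuisance[["r"]]
      p <- r / (r + mu); q <- mu / (r + mu)
      v <- r * q / p^2
      list(var = v,
           c3 = r * q * (1 + q) / p^3,
           c4 = r * q * (1 + 4 * q + q^2) / p^4 + 3 * v^2)
    })
  out$mu <- mu
  out$skew <- out$c3 / out$var^1.5
  out$kurt <- out$c4 / out$var^2
  out[c("mu", "var", "c3", "c4", "skew", "kurt")]
}

# inverse link and its first two derivatives w.r.t. the linear predictor
linkinv_derivs <- function(link, eta) {
  switch(link,
    identity = list(mu = eta, dmu = rep_len(1, length(eta)),
                    d2mu = rep_len(0, length(eta))),
    log = {
      mu <- exp(eta)
      list(mu = mu, dmu = mu, d2mu = mu)
    },
    logit = {
      mu <- stats::plogis(eta)       # stable for large |eta|
      dmu <- mu * (1 - mu)
      list(mu = mu, dmu = dmu, d2mu = dmu * (1 - 2 * mu))
    })
}

# variance function V(mu) and derivatives in mu (nuisance held fixed)
var_derivs <- function(margin, mu) {
  n <- length(mu)
  switch(margin$family,
    gaussian  = list(v = rep_len(margin$nuisance[["tau2"]], n),
                     dv = rep_len(0, n), d2v = rep_len(0, n)),
    bernoulli = list(v = mu * (1 - mu), dv = 1 - 2 * mu,
                     d2v = rep_len(-2, n)),
    poisson   = list(v = mu, dv = rep_len(1, n), d2v = rep_len(0, n)),
    nbinom = {
      r <- margin$nuisance[["r"]]
      list(v = mu + mu^2 / r, dv = 1 + 2 * mu / r, d2v = rep_len(2 / r, n))
    })
}

# d log f / d mu and d^2 log f / d mu^2 (nuisance fixed); for all four
# families d log f/d mu = (y - mu)/V(mu)
logf_mu_derivs <- function(margin, y, mu) {
  vd <- var_derivs(margin, mu)
  d1 <- (y - mu) / vd$v
  d2 <- (-vd$v - (y - mu) * vd$dv) / vd$v^2
  list(d1 = d1, d2 = d2)
}

#' Mean and variance derivatives under the link
#'
#' Computes `mu = g^{-1}(x'beta)` and the gradient and Hessian in
#' `beta` of both the mean and the variance function, by the chain
#' rule through the inverse link.  Overflow-safe forms of the logistic
#' link are used; no clipping of the linear predictor.
#'
#' @inheritParams margin_logpdf
#' @param x_row covariate row (length p).
#' @param beta coefficient vector (length p).
#' @return list with `mu`, `grad_mu`, `hess_mu`, `var`, `grad_var`,
#'   `hess_var`.
#' @export
mean_var_derivs <- function(margin, x_row, beta) {
  eta <- sum(x_row * beta)
  li <- linkinv_derivs(margin$link, eta)
  xx <- tcrossprod(x_row)
  vd <- var_derivs(margin, li$mu)
  list(mu = li$mu,
       grad_mu = li$dmu * x_row,
       hess_mu = li$d2mu * xx,
       var = vd$v,
       grad_var = vd$dv * li$dmu * x_row,
       hess_var = vd$d2v * li$dmu^2 * xx + vd$dv * li$d2mu * xx)
}

# derivative of log f and of V w.r.t. the nuisance parameter (vectorized)
logf_nuis_deriv <- function(margin, y, mu) {
  switch(margin$family,
    gaussian = {
      t2 <- margin$nuisance[["tau2"]]
      list(dlogf = -0.5 / t2 + (y - mu)^2 / (2 * t2^2),
           dvar = rep_len(1, length(mu)))
    },
    nbinom = {
      r <- margin$nuisance[["r"]]
      list(dlogf = digamma(y + r) - digamma(r) + log(r) + 1 -
             log(r + mu) - (y + r) / (r + mu),
           dvar = -mu^2 / r^2)
    },
    list(dlogf = numeric(length(mu)), dvar = numeric(length(mu))))
}

# quantile of the base pmf, used to truncate discrete enumerations
margin_upper_quantile <- function(margin, mu, p = 1 - 1e-12) {
  switch(margin$family,
    bernoulli = 1,
    poisson   = stats::qpois(p, max(mu)),
    nbinom    = stats::qnbinom(p, size = margin$nuisance[["r"]],
                               mu = max(mu)),
    stop("discrete quantile undefined for family ", margin$family))
}
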