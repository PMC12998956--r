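#' Dependence structures for the tilt matrix Gamma
#'
#' The within-unit dependence of an approximate-copula model is carried
#' by a positive semidefinite matrix `Gamma` whose off-diagonal entries
#' act approximately as correlations of the standardized residuals and
#' whose diagonal inflates marginal variances.  Four parameterizations
#' are supported:
#'
#' * `gamma_vc()`: variance components, `Gamma = sum_j theta_j Omega_j`
#'   with known PSD `Omega_j` and `theta_j >= 0`.  `omega` may be the
#'   keyword `"intercept"` (`Omega = 11'`, the random-intercept analogue),
#'   `"identity"`, or a list of matrices / functions of the unit size `d`.
#' * `gamma_ar1()`: autoregressive, entries `sigma2 * rho^|k-l|`,
#'   `rho` in (-1, 1).
#' * `gamma_cs()`: compound symmetry,
#'   `sigma2 * [rho 11' + (1-rho) I]`, `rho` in `[-1/(d_max-1), 1]`.
#' * `gamma_unstr(d)`: unstructured `Gamma = L L'` through the lower
#'   Cholesky factor `L`; the only constraint is `diag(L) >= 0` and the
#'   free parameters are `vech(L)`.
#' * `gamma_fixed(G)`: a known constant matrix (no free parameters).
#'
#' @param omega PSD basis specification for the VC structure (see above).
#' @param d dimension of the unstructured factor.
#' @param G fixed PSD matrix.
#' @return an object of class `c("ac_gamma_<kind>", "ac_gamma")`.
#' @name gamma_structures
NULL

#' @rdname gamma_structures
#' @export
gamma_vc <- function(omega = "intercept") {
  if (is.character(omega))
    omega <- switch(match.arg(omega, c("intercept", "identity")),
      intercept = list(function(d) matrix(1, d, d)),
      identity  = list(function(d) diag(d)))
  if (is.matrix(omega)) omega <- list(omega)
  stopifnot(is.list(omega), length(omega) >= 1L)
  structure(list(kind = "vc", omega = omega),
            class = c("ac_gamma_vc", "ac_gamma"))
}

#' @rdname gamma_structures
#' @export
gamma_ar1 <- function()
  structure(list(kind = "ar1"), class = c("ac_gamma_ar1", "ac_gamma"))

#' @rdname gamma_structures
#' @export
gamma_cs <- function()
  structure(list(kind = "cs", d_max = NULL),
            class = c("ac_gamma_cs", "ac_gamma"))

#' @rdname gamma_structures
#' @export
gamma_unstr <- function(d) {
  stopifnot(d >= 1)
  structure(list(kind = "unstr", d = as.integer(d)),
            class = c("ac_gamma_unstr", "ac_gamma"))
}

#' @rdname gamma_structures
#' @export
gamma_fixed <- function(G) {
  G <- as.matrix(G)
  stopifnot(isSymmetric(G, tol = 1e-8))
  structure(list(kind = "fixed", G = G),
            class = c("ac_gamma_fixed", "ac_gamma"))
}

#' @export
print.ac_gamma <- function(x, ...) {
  cat("<ac_gamma> ", x$kind, " structure\n", sep = "")
  invisible(x)
}

vc_omegas <- function(struct, d)
  lapply(struct$omega, function(o) if (is.function(o)) o(d) else {
    stopifnot(nrow(o) == d); o
  })

# number of free dependence parameters
gamma_npar <- function(struct, d) {
  switch(struct$kind,
    vc = length(struct$omega), ar1 = 2L, cs = 2L,
    unstr = struct$d * (struct$d + 1L) / 2L, fixed = 0L)
}

gamma_par_names <- function(struct, d) {
  switch(struct$kind,
    vc = paste0("theta", seq_along(struct$omega)),
    ar1 = c("sigma2", "rho"), cs = c("sigma2", "rho"),
    unstr = {
      ij <- which(lower.tri(diag(struct$d), diag = TRUE), arr.ind = TRUE)
      ij <- ij[order(ij[, 2L], ij[, 1L]), , drop = FALSE]
      paste0("L", ij[, 1L], ".", ij[, 2L])
    },
    fixed = character(0))
}

# vech/unvech in column-major lower-triangle order
vech <- function(L) L[lower.tri(L, diag = TRUE)]
unvech <- function(x, d) {
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- x
  L
}

cs_rho_min <- function(d_max) if (d_max <= 1L) -1 else -1 / (d_max - 1)

check_gamma_par <- function(struct, theta, d) {
  switch(struct$kind,
    vc = if (any(theta < 0))
      stop("variance components must be nonnegative"),
    ar1 = if (theta[1L] < 0 || abs(theta[2L]) >= 1)
      stop("AR1 requires sigma2 >= 0 and |rho| < 1"),
    cs = {
      lo <- cs_rho_min(if (is.null(struct$d_max)) d else struct$d_max)
      if (theta[1L] < 0 || theta[2L] < lo - 1e-12 || theta[2L] > 1 + 1e-12)
        stop("CS requires sigma2 >= 0 and rho in [", format(lo), ", 1]")
    },
    unstr = if (any(diag(unvech(theta, struct$d)) < 0))
      stop("Cholesky factor requires a nonnegative diagonal"),
    fixed = NULL)
  invisible(TRUE)
}

#' Materialize a dependence structure as a dense PSD matrix
#'
#' @param struct a structure from [gamma_structures].
#' @param theta free parameter vector of the structure (`theta` for VC,
#'   `(sigma2, rho)` for AR1/CS, `vech(L)` for unstructured; ignored for
#'   fixed structures).
#' @param d unit dimension (must match `dim(L)` for unstructured).
#' @return the symmetric PSD matrix `Gamma` of dimension `d x d`.
#' @export
gamma_materialize <- function(struct, theta, d) {
  check_gamma_par(struct, theta, d)
  switch(struct$kind,
    vc = Reduce(`+`, Map(`*`, as.list(theta), vc_omegas(struct, d))),
    ar1 = theta[1L] * theta[2L]^abs(outer(seq_len(d), seq_len(d), `-`)),
    cs = theta[1L] * (theta[2L] * matrix(1, d, d) +
                        (1 - theta[2L]) * diag(d)),
    unstr = {
      if (d != struct$d) stop("dimension mismatch: structure has d = ",
                              struct$d, " but unit has d = ", d)
      tcrossprod(unvech(theta, d))
    },
    fixed = {
      if (d != nrow(struct$G)) stop("dimension mismatch for fixed Gamma")
      struct$G
    })
}

# list of dGamma/dtheta_k matrices
gamma_deriv <- function(struct, theta, d) {
  switch(struct$kind,
    vc = vc_omegas(struct, d),
    ar1 = {
      D <- abs(outer(seq_len(d), seq_len(d), `-`))
      dr <- D * theta[2L]^pmax(D - 1L, 0L)
      dr[D == 0L] <- 0
      list(theta[2L]^D, theta[1L] * dr)
    },
    cs = list(theta[2L] * matrix(1, d, d) + (1 - theta[2L]) * diag(d),
              theta[1L] * (matrix(1, d, d) - diag(d))),
    unstr = {
      L <- unvech(theta, d)
      ij <- which(lower.tri(L, diag = TRUE), arr.ind = TRUE)
      ij <- ij[order(ij[, 2L], ij[, 1L]), , drop = FALSE]
      lapply(seq_len(nrow(ij)), function(k) {
        E <- matrix(0, d, d); E[ij[k, 1L], ij[k, 2L]] <- 1
        M <- E %*% t(L); M + t(M)
      })
    },
    fixed = list())
}

#' Trace and residual quadratic form of Gamma
#'
#' The loglikelihood depends on the dependence parameters only through
#' `tr(Gamma)` and `r' Gamma r` per unit; this computes both.
#'
#' @inheritParams gamma_materialize
#' @param r standardized residual vector of length `d`.
#' @return a list with nonnegative scalars `tr` and `quad`.
#' @export
gamma_trace_quad <- function(struct, theta, r) {
  d <- length(r)
  if (struct$kind == "vc") {
    om <- vc_omegas(struct, d)
    b <- vapply(om, function(o) drop(crossprod(r, o %*% r)), 0)
    cc <- vapply(om, function(o) sum(diag(o)), 0)
    return(list(tr = sum(theta * cc), quad = sum(theta * b),
                b = b, c = cc))
  }
  if (struct$kind == "unstr") {
    L <- unvech(theta, struct$d)
    u <- drop(crossprod(L, r))
    return(list(tr = sum(L^2), quad = sum(u^2)))
  }
  G <- gamma_materialize(struct, theta, d)
  list(tr = sum(diag(G)), quad = drop(crossprod(r, G %*% r)))
}

#' Derivatives of trace and quadratic form in the structure parameters
#'
#' Exact partial derivatives of `tr(Gamma)` and `r' Gamma r` with
#' respect to the structure's free parameters.  VC and unstructured
#' Cholesky use closed forms (`d tr/d theta_j = tr(Omega_j)`,
#' `d quad/d l_ab = 2 r_a (L'r)_b`); AR1/CS differentiate the entries
#' directly.
#'
#' @inheritParams gamma_trace_quad
#' @return list with vectors `dtr` and `dquad` of length
#'   `gamma_npar(struct, d)`.
#' @export
gamma_grad_trace_quad <- function(struct, theta, r) {
  d <- length(r)
  switch(struct$kind,
    vc = {
      om <- vc_omegas(struct, d)
      list(dtr = vapply(om, function(o) sum(diag(o)), 0),
           dquad = vapply(om, function(o) drop(crossprod(r, o %*% r)), 0))
    },
    unstr = {
      L <- unvech(theta, struct$d)
      u <- drop(crossprod(L, r))                 # L'r
      ij <- which(lower.tri(L, diag = TRUE), arr.ind = TRUE)
      ij <- ij[order(ij[, 2L], ij[, 1L]), , drop = FALSE]
      list(dtr = 2 * L[ij],
           dquad = 2 * r[ij[, 1L]] * u[ij[, 2L]])
    },
    fixed = list(dtr = numeric(0), dquad = numeric(0)),
    {
      dG <- gamma_deriv(struct, theta, d)
      list(dtr = vapply(dG, function(g) sum(diag(g)), 0),
           dquad = vapply(dG, function(g) drop(crossprod(r, g %*% r)), 0))
    })
}

# -- unconstrained transforms used by the joint quasi-Newton phase ------
# theta  -> psi (free scale), psi -> theta, and d theta/d psi (diagonal
# Jacobian except for CS/AR1 where it is still elementwise)
gamma_to_free <- function(struct, theta) {
  switch(struct$kind,
    vc = log(pmax(theta, 1e-12)),
    ar1 = c(log(max(theta[1L], 1e-12)), atanh(theta[2L])),
    cs = {
      lo <- cs_rho_min(struct$d_max %||% 2L)
      z <- (theta[2L] - lo) / (1 - lo)
      c(log(max(theta[1L], 1e-12)),
        stats::qlogis(min(max(z, 1e-10), 1 - 1e-10)))
    },
    unstr = {
      d <- struct$d
      L <- unvech(theta, d)
      diag(L) <- log(pmax(diag(L), 1e-10))
      vech(L)
    },
    fixed = numeric(0))
}

gamma_from_free <- function(struct, psi) {
  switch(struct$kind,
    vc = exp(psi),
    ar1 = c(exp(psi[1L]), tanh(psi[2L])),
    cs = {
      lo <- cs_rho_min(struct$d_max %||% 2L)
      c(exp(psi[1L]), lo + (1 - lo) * stats::plogis(psi[2L]))
    },
    unstr = {
      d <- struct$d
      L <- unvech(psi, d)
      diag(L) <- exp(diag(L))
      vech(L)
    },
    fixed = numeric(0))
}

# d theta_k / d psi_k, elementwise (all transforms are coordinatewise)
gamma_free_jac <- function(struct, psi) {
  switch(struct$kind,
    vc = exp(psi),
    ar1 = c(exp(psi[1L]), 1 / cosh(psi[2L])^2),
    cs = {
      lo <- cs_rho_min(struct$d_max %||% 2L)
      p <- stats::plogis(psi[2L])
      c(exp(psi[1L]), (1 - lo) * p * (1 - p))
    },
    unstr = {
      d <- struct$d
      J <- unvech(rep(1, d * (d + 1) / 2), d)
      diag(J) <- exp(diag(unvech(psi, d)))
      vech(J)
    },
    fixed = numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
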