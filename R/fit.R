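#' Control parameters for model fitting
#'
#' @param block_iters maximum block-ascent cycles before switching to
#'   the joint quasi-Newton phase.
#' @param switch_tol ascent gain below which the block phase stops.
#' @param gtol_scale gradient tolerance scale; convergence requires the
#'   free-scale gradient sup-norm below
#'   `gtol_scale * (1 + |loglik| / n)`.
#' @param qn_maxit maximum quasi-Newton (BFGS) iterations.
#' @param qn_reltol relative-improvement stopping tolerance of the
#'   quasi-Newton phase.
#' @param newton_polish maximum Newton clean-up cycles after the
#'   quasi-Newton phase (approximate-Hessian steps on `beta` plus BFGS
#'   touch-ups on the dependence block) applied while the joint
#'   gradient is above tolerance.
#' @param mm_sweeps MM sweeps per block-ascent cycle (VC structure).
#' @param verbose print per-cycle loglikelihoods?
#' @return a list of class `"acm_control"`.
#' @export
acm_control <- function(block_iters = 30L, switch_tol = 1e-4,
                        gtol_scale = 1e-6, qn_maxit = 500L,
                        qn_reltol = 1e-12, newton_polish = 25L,
                        mm_sweeps = 5L, verbose = FALSE) {
  structure(list(block_iters = block_iters, switch_tol = switch_tol,
                 gtol_scale = gtol_scale, qn_maxit = qn_maxit,
                 qn_reltol = qn_reltol, newton_polish = newton_polish,
                 mm_sweeps = mm_sweeps, verbose = verbose),
            class = "acm_control")
}

# independence-model IRLS fit (base GLM over the stacked mixed-family
# design); supplies starting values for beta and the nuisances
fit_base_glm <- function(units, maxit = 60L) {
  X <- units$X; y <- units$y
  beta <- numeric(units$P)
  nn <- nuis_names(units)
  nuis <- stats::setNames(rep(1, length(nn)), nn)
  margs <- current_margins(units, nuis)
  base_ll <- function(b) {
    eta <- drop(X %*% b)
    out <- 0
    for (f in names(margs)) {
      idx <- units$fam_row == f
      mu <- linkinv_derivs(margs[[f]]$link, eta[idx])$mu
      out <- out + sum(margin_logpdf(margs[[f]], y[idx], mu))
    }
    out
  }
  ll <- base_ll(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    scr <- numeric(length(y)); w <- numeric(length(y))
    for (f in names(margs)) {
      m <- margs[[f]]; idx <- units$fam_row == f
      li <- linkinv_derivs(m$link, eta[idx])
      vd <- var_derivs(m, li$mu)
      if (f == "bernoulli") {                 # cancellation-free forms
        scr[idx] <- y[idx] - li$mu
        w[idx] <- vd$v
      } else {
        scr[idx] <- (y[idx] - li$mu) / vd$v * li$dmu
        w[idx] <- li$dmu^2 / vd$v
      }
    }
    g <- drop(crossprod(X, scr))
    H <- crossprod(X * sqrt(w)) + diag(1e-8, units$P)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    # damped Fisher scoring: halve until the base loglik is no worse
    moved <- FALSE
    for (half in 0:25) {
      llc <- base_ll(beta + step)
      if (is.finite(llc) && llc >= ll - 1e-12) {
        beta <- beta + step; moved <- llc > ll; ll <- llc
        break
      }
      step <- step / 2
    }
    if (!moved || max(abs(step)) < 1e-10) break
  }
  mu <- numeric(length(y))
  eta <- drop(X %*% beta)
  for (f in names(current_margins(units, nuis)))
    mu[units$fam_row == f] <-
      linkinv_derivs(units$templates[[f]]$link, eta[units$fam_row == f])$mu
  if ("tau2" %in% nn)
    nuis["tau2"] <- max(mean((y - mu)[units$fam_row == "gaussian"]^2),
                        1e-8)
  if ("r" %in% nn) {
    idx <- units$fam_row == "nbinom"
    mbar <- mu[idx]; res2 <- (y[idx] - mbar)^2
    excess <- mean(res2 - mbar)
    nuis["r"] <- min(max(mean(mbar^2) / max(excess, 1e-3), 0.05), 1e4)
  }
  list(beta = beta, nuis = nuis)
}

# dependence-parameter starting values following the initialization
# recipe: MM for variance components; MM with rho = 0 for AR1/CS scale;
# Cholesky of the sample correlation of the responses for unstructured
init_theta <- function(units, beta, nuis) {
  st <- units$struct
  switch(st$kind,
    vc = {
      theta <- rep(0.1, length(st$omega))
      bc <- vc_bc(units, beta, nuis)
      for (k in 1:50) {
        new <- ac_mm_update_theta(units, beta, theta, nuis, bc = bc)
        if (max(abs(new - theta)) < 1e-8) { theta <- new; break }
        theta <- new
      }
      theta
    },
    ar1 = , cs = {
      tmp <- units; tmp$struct <- gamma_vc("identity")
      s2 <- 0.1
      bc <- vc_bc(tmp, beta, nuis)
      for (k in 1:50)
        s2 <- ac_mm_update_theta(tmp, beta, s2, nuis, bc = bc)
      c(max(s2, 1e-6), 0)
    },
    unstr = {
      d <- st$d
      Y <- matrix(units$y[units$groups[[1L]]$rows], ncol = d)
      C <- suppressWarnings(stats::cor(Y))
      C[!is.finite(C)] <- 0; diag(C) <- 1
      L <- t(chol(C + diag(1e-3, d)))
      vech(L)
    },
    fixed = numeric(0))
}

#' Fit an approximate-copula model to assembled units
#'
#' The low-level fitter behind [acm()].  Starts `beta` at the
#' independent base-model MLE and the dependence parameters at
#' MM / sample-correlation initial values, runs monotone block ascent
#' (Newton on `beta` with the NSD approximate Hessian and Armijo step
#' halving; MM or BFGS on the dependence block; profile Newton on the
#' nuisances), then polishes jointly with BFGS on transformed
#' unconstrained parameters.  Non-convergence is reported through the
#' `converged` flag, never as an error.
#'
#' @param units an [ac_units()] object.
#' @param control an [acm_control()] list.
#' @param start optional warm start, a list with `beta`, `theta`,
#'   `nuis`; skips the base-GLM / MM initialization.
#' @param sandwich compute the sandwich covariance? (Skipping it makes
#'   repeated refits, e.g. per-SNP likelihood-ratio tests, cheaper.)
#' @return an object of class `"acm"`.
#' @export
acm_fit <- function(units, control = acm_control(), start = NULL,
                    sandwich = TRUE) {
  if (is.null(start)) {
    base <- fit_base_glm(units)
    beta <- base$beta; nuis <- base$nuis
    theta <- init_theta(units, beta, nuis)
  } else {
    beta <- start$beta; theta <- start$theta
    nuis <- start$nuis %||% numeric(0)
  }
  m <- length(theta)
  ll <- ac_loglik(units, beta, theta, nuis)
  trace <- data.frame(phase = "init", iter = 0L, loglik = ll)
  for (it in seq_len(control$block_iters)) {
    ll_prev <- ll
    # -- beta: Newton with the NSD approximate Hessian, step halving
    ev <- ac_eval(units, beta, theta, nuis)
    H <- ac_hessian_beta(units, beta, theta, nuis, exact = FALSE)
    step <- tryCatch(solve(-H + diag(1e-8, units$P), ev$score_beta),
                     error = function(e) ev$score_beta * 1e-3)
    for (half in 0:20) {
      cand <- beta + step
      llc <- tryCatch(ac_loglik(units, cand, theta, nuis),
                      error = function(e) -Inf)
      if (is.finite(llc) && llc >= ll - 1e-12) {
        beta <- cand; ll <- llc; break
      }
      step <- step / 2
    }
    # -- dependence block
    if (m > 0L) {
      if (units$struct$kind == "vc") {
        bc <- vc_bc(units, beta, nuis)
        for (k in seq_len(control$mm_sweeps))
          theta <- ac_mm_update_theta(units, beta, theta, nuis, bc = bc)
      } else {
        theta <- theta_profile_optimize(units, beta, theta, nuis,
                                        maxit = 30L)
      }
      ll <- ac_loglik(units, beta, theta, nuis)
    }
    # -- nuisances
    for (nm in names(nuis))
      nuis <- ac_nuisance_step(units, beta, theta, nuis, nm)
    ll <- ac_loglik(units, beta, theta, nuis)
    trace <- rbind(trace, data.frame(phase = "block", iter = it,
                                     loglik = ll))
    if (control$verbose)
      message("block ", it, "  loglik ", format(ll, digits = 10))
    if (ll - ll_prev < control$switch_tol) break
  }
  # -- joint quasi-Newton polish on the free scale
  if (control$qn_maxit > 0L) {
    psi <- pack_free(units, beta, theta, nuis)
    opt <- tryCatch(
      stats::optim(psi, function(p) free_negloglik(units, p),
                   function(p) -free_grad(units, p), method = "BFGS",
                   control = list(maxit = control$qn_maxit,
                                  reltol = control$qn_reltol)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) &&
        -opt$value >= ll - 1e-8) {
      pp <- unpack_free(units, opt$par)
      beta <- pp$beta; theta <- pp$theta; nuis <- pp$nuis
      ll <- -opt$value
      trace <- rbind(trace, data.frame(phase = "qn",
                                       iter = opt$counts[["function"]],
                                       loglik = ll))
    }
  }
  gtol <- control$gtol_scale * (1 + abs(ll) / units$n)
  kk <- tryCatch(kkt_measure(units, beta, theta, nuis),
                 error = function(e) list(norm = NA_real_,
                                          active = integer(0)))
  score_norm <- kk$norm
  # joint Newton clean-up: full cross-coupled curvature drives the
  # remaining gradient down quadratically where block ascent crawls
  if (is.finite(score_norm) && score_norm >= max(gtol, 1e-4) &&
      control$newton_polish > 0L) {
    jn <- tryCatch(joint_newton(units, beta, theta, nuis,
                                maxit = control$newton_polish,
                                gtol = max(gtol, 1e-5)),
                   error = function(e) NULL)
    if (!is.null(jn) && is.finite(jn$loglik) && jn$loglik >= ll - 1e-8) {
      beta <- jn$beta; theta <- jn$theta; nuis <- jn$nuis
      ll <- jn$loglik
      trace <- rbind(trace, data.frame(phase = "polish",
                                       iter = jn$iters, loglik = ll))
      kk <- tryCatch(kkt_measure(units, beta, theta, nuis),
                     error = function(e) list(norm = NA_real_,
                                              active = integer(0)))
      score_norm <- kk$norm
    }
  }
  converged <- is.finite(score_norm) && score_norm < max(gtol, 1e-4)
  # dependence parameters on the nonnegativity boundary: a coordinate
  # pinned at (numerically) zero with an inward-pointing gradient is a
  # KKT-legitimate boundary solution; report it as exactly zero
  boundary <- logical(m)
  boundary[kk$active[kk$active <= m]] <- TRUE
  boundary <- boundary | theta < 1e-8 &
    seq_len(m) %in% (lb_indices(units$struct, 0L))
  theta_rep <- theta
  theta_rep[boundary] <- 0
  sw <- if (sandwich)
    tryCatch(ac_sandwich(units, beta, theta, nuis),
             error = function(e) NULL)
  else NULL
  parnames <- c(colnames(units$X) %||% paste0("beta", seq_len(units$P)),
                gamma_par_names(units$struct, 0L), names(nuis))
  structure(list(beta = stats::setNames(beta, parnames[seq_len(units$P)]),
                 theta = theta_rep, nuis = nuis, loglik = ll,
                 score_norm = score_norm, converged = converged,
                 boundary = boundary, vcov = sw$vcov,
                 vcov_pseudo = isTRUE(sw$pseudo),
                 trace = trace, units = units, parnames = parnames),
            class = "acm")
}

#' Approximate-copula regression models
#'
#' Fits a longitudinal or multivariate approximate-copula regression by
#' maximum likelihood.  With a vector response and a grouping `id`,
#' each subject's repeated measurements share one base family and the
#' within-subject dependence follows `structure` (variance components
#' by default).  With a matrix response (`cbind(...)` on the left-hand
#' side), each row is one unit, each column may have its own base
#' family, and the default dependence is an unstructured Cholesky
#' factor.  Standard errors are robust sandwich estimates over the
#' full `(beta, theta, nuisance)` block.
#'
#' @param formula model formula; the left-hand side is a vector
#'   (longitudinal) or a `cbind()` matrix (multivariate).
#' @param data data frame holding the variables.
#' @param id grouping variable for longitudinal data: a column name or
#'   a vector.  Ignored for matrix responses.
#' @param family base family: one string (or [ac_margin()]) for
#'   longitudinal data, or one per response column for multivariate
#'   data.
#' @param structure a [gamma_structures] object, or one of
#'   `"vc"`, `"ar1"`, `"cs"`, `"unstructured"`, `"none"` (independence,
#'   a fixed zero `Gamma`).
#' @param control an [acm_control()] list.
#' @return a fitted `"acm"` model with methods `print`, `summary`,
#'   `coef`, `vcov`, `logLik`, `fitted`, `residuals`, and `simulate`.
#' @examples
#' set.seed(7)
#' sim <- sim_longitudinal(n = 300, d = 3, family = "poisson",
#'                         theta = 0.1, p = 2)
#' fit <- acm(y ~ x1 + x2, data = sim$data, id = "id",
#'            family = "poisson")
#' summary(fit)
#' @export
acm <- function(formula, data, id = NULL, family = "gaussian",
                structure = NULL, control = acm_control()) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  as_margin <- function(f) if (inherits(f, "ac_margin")) f
    else ac_margin(f)
  if (is.matrix(y) && ncol(y) > 1L) {       # multivariate: row = unit
    d <- ncol(y); n <- nrow(y); p <- ncol(X)
    margins <- lapply(if (length(family) == 1L)
      rep(list(family), d) else as.list(family), as_margin)
    if (length(margins) != d)
      stop("need one family per response column")
    Xs <- matrix(0, n * d, p * d)
    cn <- character(p * d)
    trait <- colnames(y) %||% paste0("y", seq_len(d))
    for (j in seq_len(d)) {
      Xs[seq(j, n * d, by = d), (j - 1L) * p + seq_len(p)] <- X
      cn[(j - 1L) * p + seq_len(p)] <- paste(trait[j], colnames(X),
                                             sep = ":")
    }
    colnames(Xs) <- cn
    struct <- resolve_structure(structure, d, default = "unstructured")
    units <- ac_units(as.numeric(t(y)), Xs, rep(seq_len(n), each = d),
                      margins, struct)
  } else {                                   # longitudinal
    if (is.null(id)) stop("longitudinal fits need a grouping 'id'")
    idv <- if (is.character(id) && length(id) == 1L) data[[id]] else id
    if (length(idv) != length(y)) {
      keep <- suppressWarnings(as.integer(rownames(mf)))
      if (!anyNA(keep)) idv <- idv[keep]
      if (length(idv) != length(y))
        stop("'id' cannot be aligned with the model frame")
    }
    margin <- as_margin(if (length(family) == 1L) family else
      stop("longitudinal fits use a single family"))
    d_max <- max(table(idv))
    struct <- resolve_structure(structure, d_max, default = "vc")
    units <- ac_units(as.numeric(y), X, idv, margin, struct)
  }
  fit <- acm_fit(units, control)
  fit$call <- match.call()
  fit
}

resolve_structure <- function(structure, d, default) {
  if (inherits(structure, "ac_gamma")) return(structure)
  key <- structure %||% default
  switch(key,
    vc = gamma_vc("intercept"),
    ar1 = gamma_ar1(),
    cs = gamma_cs(),
    unstructured = gamma_unstr(d),
    none = gamma_fixed(matrix(0, d, d)),
    stop("unknown structure '", key, "'"))
}

#' @export
print.acm <- function(x, ...) {
  cat("Approximate-copula model fit\n")
  cat("  units:", x$units$n, " observations:", length(x$units$y),
      " dependence:", x$units$struct$kind, "\n")
  cat("  loglik:", format(x$loglik, digits = 8),
      " converged:", x$converged, "\n")
  cat("  coefficients:\n")
  print(round(x$beta, 4))
  if (length(x$theta))
    cat("  dependence parameters:",
        paste(format(round(x$theta, 4)), collapse = " "), "\n")
  if (length(x$nuis))
    cat("  nuisance:", paste(names(x$nuis), "=",
                             format(round(x$nuis, 4)), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
coef.acm <- function(object, full = FALSE, ...) {
  if (!full) return(object$beta)
  stats::setNames(c(object$beta, object$theta, object$nuis),
                  object$parnames)
}

#' @export
vcov.acm <- function(object, ...) object$vcov

#' @export
logLik.acm <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- length(object$parnames)
  attr(val, "nobs") <- object$units$n
  class(val) <- "logLik"
  val
}

#' @export
fitted.acm <- function(object, ...) {
  units <- object$units
  ac_eval(units, object$beta, object$theta, object$nuis,
          score = FALSE)$mu
}

#' @export
residuals.acm <- function(object, type = c("standardized", "response"),
                          ...) {
  type <- match.arg(type)
  ev <- ac_eval(object$units, object$beta, object$theta, object$nuis,
                score = FALSE)
  if (type == "response") object$units$y - ev$mu else ev$r
}

#' @export
summary.acm <- function(object, level = 0.95, ...) {
  est <- coef(object, full = TRUE)
  se <- if (!is.null(object$vcov)) sqrt(pmax(diag(object$vcov), 0))
  else rep(NA_real_, length(est))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(1 - (1 - level) / 2)
  tab <- data.frame(parameter = object$parnames, estimate = est,
                    std_error = se, z = z, p_value = p,
                    ci_low = est - q * se, ci_high = est + q * se,
                    row.names = NULL)
  structure(list(table = tab, loglik = object$loglik,
                 converged = object$converged,
                 boundary = object$boundary,
                 n = object$units$n), class = "summary.acm")
}

#' @export
print.summary.acm <- function(x, ...) {
  cat("Approximate-copula model:", x$n, "units, loglik",
      format(x$loglik, digits = 8), "\n")
  if (!x$converged) cat("  ** fit did not meet the gradient tolerance\n")
  if (any(x$boundary))
    cat("  ** dependence estimate on the nonnegativity boundary;",
        "SEs are from the unconstrained sandwich\n")
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a fit summary as TSV
#'
#' Columns `parameter`, `estimate`, `std_error`, `z`, `p_value`,
#' `ci_low`, `ci_high`.
#'
#' @param fit an `"acm"` object.
#' @param path output file.
#' @export
write_acm_summary <- function(fit, path) {
  utils::write.table(summary(fit)$table, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
simulate.acm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  units <- object$units
  mu <- fitted(object)
  margs <- current_margins(units, object$nuis)
  out <- matrix(0, length(units$y), nsim)
  for (s in seq_len(nsim)) {
    for (g in units$groups) {
      G <- gamma_materialize(units$struct, object$theta, g$d)
      Mu <- matrix(mu[g$rows], ncol = g$d)
      cols <- lapply(seq_len(g$d), function(j)
        margs[[units$fam_row[g$rows[1L, j]]]])
      out[g$rows, s] <- .sample_tilted_matrix(cols, Mu, G)
    }
  }
  colnames(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}
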