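#' Assemble clustered data into sampling units
#'
#' Internal-but-exported constructor for the flat representation the
#' likelihood machinery works on: responses stacked over all units,
#' the corresponding design rows, a unit index, one base margin per
#' within-unit position, and a dependence structure.  [acm()] builds
#' this from a formula; tests and simulators can build it directly.
#'
#' @param y stacked response vector (length `N = sum(d_i)`).
#' @param X stacked design matrix (`N x P`).
#' @param unit unit identifier per row (any type; converted to
#'   consecutive integers in order of first appearance).
#' @param margins a single [ac_margin()] shared by all positions, or a
#'   list of one margin per within-unit position (requires balanced
#'   units).
#' @param struct a dependence structure from [gamma_structures].
#' @return an object of class `"ac_units"`.
#' @export
ac_units <- function(y, X, unit, margins, struct) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(unit) == length(y))
  uid <- match(unit, unique(unit))
  ord <- order(uid)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; uid <- uid[ord]
  d_i <- tabulate(uid)
  pos <- sequence(d_i)
  if (inherits(margins, "ac_margin")) {
    fam_row <- rep(margins$family, length(y))
    templates <- stats::setNames(list(margins), margins$family)
  } else {
    if (length(unique(d_i)) != 1L || length(margins) != d_i[1L])
      stop("a list of margins requires balanced units of matching size")
    fams <- vapply(margins, `[[`, "", "family")
    fam_row <- fams[pos]
    templates <- margins[!duplicated(fams)]
    names(templates) <- fams[!duplicated(fams)]
  }
  for (f in names(templates)) check_support(templates[[f]],
                                            y[fam_row == f])
  if (inherits(struct, "ac_gamma_cs")) struct$d_max <- max(d_i)
  # row-index matrix per distinct unit size, for batched per-unit algebra
  groups <- lapply(sort(unique(d_i)), function(d) {
    us <- which(d_i == d)
    rows <- matrix(which(uid %in% us), ncol = d, byrow = TRUE)
    list(d = d, units = us, rows = rows)
  })
  fam_idx <- lapply(stats::setNames(names(templates),
                                    names(templates)),
                    function(f) which(fam_row == f))
  structure(list(y = y, X = X, unit = uid, d_i = d_i, pos = pos,
                 fam_row = fam_row, fam_idx = fam_idx,
                 templates = templates,
                 struct = struct, n = max(uid), P = ncol(X),
                 groups = groups),
            class = "ac_units")
}

#' @export
print.ac_units <- function(x, ...) {
  cat("<ac_units>", x$n, "units,", length(x$y), "observations,",
      x$P, "design columns;", x$struct$kind, "dependence\n")
  invisible(x)
}

nuis_names <- function(units) {
  c(if ("gaussian" %in% names(units$templates)) "tau2",
    if ("nbinom" %in% names(units$templates)) "r")
}

# margins with current nuisance values substituted
current_margins <- function(units, nuis) {
  lapply(units$templates, function(m) {
    if (m$family == "gaussian") m$nuisance[["tau2"]] <- nuis[["tau2"]]
    if (m$family == "nbinom") m$nuisance[["r"]] <- nuis[["r"]]
    m
  })
}

# Workhorse: loglikelihood and analytic scores for (beta, theta, nuis).
# Returns row-level and unit-level ingredients reused by the Hessians
# and the sandwich estimator.
ac_eval <- function(units, beta, theta, nuis = numeric(0),
                    score = TRUE) {
  N <- length(units$y); P <- units$P
  margs <- current_margins(units, nuis)
  eta <- drop(units$X %*% beta)
  mu <- dmu <- d2mu <- s2 <- dvmu <- d2vmu <- lf <- dlf <-
    dlf_nu <- dv_nu <- numeric(N)
  for (f in names(margs)) {
    m <- margs[[f]]
    idx <- units$fam_idx[[f]] %||% which(units$fam_row == f)
    li <- linkinv_derivs(m$link, eta[idx])
    vd <- var_derivs(m, li$mu)
    mu[idx] <- li$mu; dmu[idx] <- li$dmu; d2mu[idx] <- li$d2mu
    s2[idx] <- vd$v; dvmu[idx] <- vd$dv; d2vmu[idx] <- vd$d2v
    lf[idx] <- .margin_logpdf(m, units$y[idx], li$mu)
    dlf[idx] <- (units$y[idx] - li$mu) / vd$v * li$dmu
    if (length(nuis) && f %in% c("gaussian", "nbinom")) {
      nd <- logf_nuis_deriv(m, units$y[idx], li$mu)
      dlf_nu[idx] <- nd$dlogf
      dv_nu[idx] <- nd$dvar
    }
  }
  s <- sqrt(s2)
  rres <- (units$y - mu) / s
  # guard the float boundary of saturated links (Bernoulli mu rounded
  # to exactly 0 or 1): 0/0 residuals are truly 0, +-Inf residuals are
  # capped far beyond any statistically meaningful magnitude
  if (anyNA(rres) || any(is.infinite(rres))) {
    rres[is.nan(rres)] <- 0
    rres <- pmin(pmax(rres, -1e8), 1e8)
  }
  dV <- dvmu * dmu                             # d sigma^2 / d eta
  drdeta <- -dmu / s - rres * dV / (2 * s2)
  wJ <- dmu^2 / s2                             # expected base info
  idxB <- units$fam_idx[["bernoulli"]] %||%
    which(units$fam_row == "bernoulli")
  if (length(idxB)) {
    # cancellation-free canonical-logit forms, exact in the interior
    # and finite at the saturated float boundary
    dlf[idxB] <- units$y[idxB] - mu[idxB]
    drdeta[idxB] <- -s[idxB] - rres[idxB] * (1 - 2 * mu[idxB]) / 2
    wJ[idxB] <- s2[idxB]
  }
  # per-unit tilt quantities, batched over distinct unit sizes
  Avec <- numeric(N)                           # (Gamma r)_ij per row
  den_u <- cn_u <- numeric(units$n)            # 1 + q/2 and 1 + tr/2
  m_th <- gamma_npar(units$struct, 0L)
  dquad_u <- matrix(0, units$n, m_th)
  dtr_u <- matrix(0, units$n, m_th)
  for (g in units$groups) {
    G <- gamma_materialize(units$struct, theta, g$d)
    Rg <- matrix(rres[g$rows], ncol = g$d)
    Ag <- Rg %*% G
    Avec[g$rows] <- Ag
    den_u[g$units] <- 1 + rowSums(Ag * Rg) / 2
    cn_u[g$units] <- 1 + sum(diag(G)) / 2
    if (score && m_th > 0L) {
      if (units$struct$kind == "unstr") {
        # closed form: d quad / d l_ab = 2 r_a (L'r)_b, d tr = 2 l_ab
        st <- units$struct
        L <- unvech(theta, st$d)
        ij <- which(lower.tri(L, diag = TRUE), arr.ind = TRUE)
        ij <- ij[order(ij[, 2L], ij[, 1L]), , drop = FALSE]
        RL <- Rg %*% L
        dquad_u[g$units, ] <- 2 * Rg[, ij[, 1L], drop = FALSE] *
          RL[, ij[, 2L], drop = FALSE]
        dtr_u[g$units, ] <- matrix(2 * L[ij], length(g$units), m_th,
                                   byrow = TRUE)
      } else if (units$struct$kind == "vc") {
        om <- vc_omegas(units$struct, g$d)
        for (k in seq_len(m_th)) {
          dquad_u[g$units, k] <- rowSums((Rg %*% om[[k]]) * Rg)
          dtr_u[g$units, k] <- sum(diag(om[[k]]))
        }
      } else {
        dG <- gamma_deriv(units$struct, theta, g$d)
        for (k in seq_len(m_th)) {
          dquad_u[g$units, k] <- rowSums((Rg %*% dG[[k]]) * Rg)
          dtr_u[g$units, k] <- sum(diag(dG[[k]]))
        }
      }
    }
  }
  loglik <- sum(lf) - sum(log(cn_u)) + sum(log(den_u))
  out <- list(loglik = loglik, mu = mu, s2 = s2, r = rres,
              drdeta = drdeta, dV = dV, dmu = dmu, d2mu = d2mu,
              dvmu = dvmu, d2vmu = d2vmu, dlf = dlf, wJ = wJ, A = Avec,
              den = den_u, cnorm = cn_u, dquad_u = dquad_u,
              dtr_u = dtr_u, dlf_nu = dlf_nu, dv_nu = dv_nu)
  if (!score) return(out)
  den_row <- den_u[units$unit]
  wtot <- dlf + Avec * drdeta / den_row
  out$w_beta <- wtot
  out$score_beta <- drop(crossprod(units$X, wtot))
  if (m_th > 0L)
    out$score_theta <- colSums(dquad_u / (2 * den_u)) -
      colSums(dtr_u / (2 * cn_u))
  else out$score_theta <- numeric(0)
  if (length(nuis)) {
    sn <- numeric(length(nuis)); names(sn) <- names(nuis)
    for (nm in names(nuis)) {
      fam <- if (nm == "tau2") "gaussian" else "nbinom"
      idx <- units$fam_row == fam
      drdnu <- numeric(N)
      drdnu[idx] <- -rres[idx] * dv_nu[idx] / (2 * s2[idx])
      tilt <- rowsum(Avec * drdnu, units$unit) / den_u
      sn[nm] <- sum(dlf_nu[idx]) + sum(tilt)
    }
    out$score_nuis <- sn
  } else out$score_nuis <- numeric(0)
  out
}

#' Loglikelihood of an approximate-copula model
#'
#' `sum_i [ sum_j log f_ij - log(1 + tr(Gamma_i)/2)
#'          + log(1 + r_i' Gamma_i r_i / 2) ]`.
#'
#' @param units an [ac_units()] object.
#' @param beta coefficient vector.
#' @param theta dependence parameters of `units$struct`.
#' @param nuis named nuisance vector (`tau2` and/or `r`), as required
#'   by the margins present.
#' @return scalar loglikelihood.
#' @export
ac_loglik <- function(units, beta, theta, nuis = numeric(0))
  ac_eval(units, beta, theta, nuis, score = FALSE)$loglik

#' Score of the loglikelihood
#'
#' Analytic gradient with respect to `beta` (and optionally the
#' dependence and nuisance parameters): the base-model score plus the
#' tilt correction `(J_r' Gamma r) / (1 + r' Gamma r / 2)` per unit.
#'
#' @inheritParams ac_loglik
#' @param which any of `"beta"`, `"theta"`, `"nuis"`.
#' @return named list of gradient vectors.
#' @export
ac_score <- function(units, beta, theta, nuis = numeric(0),
                     which = c("beta", "theta", "nuis")) {
  ev <- ac_eval(units, beta, theta, nuis)
  out <- list()
  if ("beta" %in% which) out$beta <- ev$score_beta
  if ("theta" %in% which) out$theta <- ev$score_theta
  if ("nuis" %in% which) out$nuis <- ev$score_nuis
  out
}

#' Hessian of the loglikelihood in beta
#'
#' `exact = TRUE` returns the full observed second differential,
#' including the indefinite curvature of the tilt term.  With
#' `exact = FALSE` it returns the negative semidefinite approximation
#' that replaces the base observed information by the expected
#' information and drops the indefinite terms; this is the matrix used
#' in the Newton phase of fitting.
#'
#' @inheritParams ac_loglik
#' @param exact exact observed Hessian, or the NSD approximation?
#' @param ev optional precomputed internal evaluation at the same
#'   parameters (for reuse by the fitter; recomputed when `NULL`).
#' @return a symmetric `P x P` matrix.
#' @export
ac_hessian_beta <- function(units, beta, theta, nuis = numeric(0),
                            exact = FALSE, ev = NULL) {
  if (is.null(ev)) ev <- ac_eval(units, beta, theta, nuis)
  X <- units$X
  den_row <- ev$den[units$unit]
  # per-unit tilt gradient g_i = sum_j A_ij dr_ij/deta_j x_j
  Gmat <- rowsum(ev$A * ev$drdeta * X, units$unit)
  if (!exact) {
    H <- -crossprod(X * sqrt(ev$wJ)) - crossprod(Gmat / ev$den)
    return((H + t(H)) / 2)
  }
  # observed base curvature d^2 ln f / d eta^2
  d1mu <- (units$y - ev$mu) / ev$s2
  d2mu_lf <- (-ev$s2 - (units$y - ev$mu) * ev$dvmu) / ev$s2^2
  w2 <- d2mu_lf * ev$dmu^2 + d1mu * ev$d2mu
  # scalar second derivative of r_ij w.r.t. eta
  s <- sqrt(ev$s2)
  h2 <- -ev$d2mu / s + ev$dmu * ev$dV / ev$s2^1.5 -
    (units$y - ev$mu) * (ev$d2vmu * ev$dmu^2 + ev$dvmu * ev$d2mu) /
      (2 * ev$s2^1.5) +
    0.75 * (units$y - ev$mu) * ev$dV^2 / ev$s2^2.5
  idxB <- units$fam_idx[["bernoulli"]] %||%
    which(units$fam_row == "bernoulli")
  if (length(idxB)) {
    # stable canonical-logit limits (see ac_eval)
    v <- ev$s2[idxB]
    w2[idxB] <- -v
    h2[idxB] <- ev$r[idxB] * ((1 - 2 * ev$mu[idxB])^2 / 4 + v)
  }
  H <- crossprod(X, X * (w2 + ev$A * h2 / den_row))
  H <- H - crossprod(Gmat / ev$den)
  # + sum_i B_i' Gamma B_i / den_i with B_i = diag(dr/deta) X_i
  B <- ev$drdeta * X
  for (g in units$groups) {
    G <- gamma_materialize(units$struct, theta, g$d)
    di <- ev$den[g$units]
    Bs <- lapply(seq_len(g$d), function(j)
      B[g$rows[, j], , drop = FALSE] / di)
    Bu <- lapply(seq_len(g$d), function(j)
      B[g$rows[, j], , drop = FALSE])
    for (j in seq_len(g$d)) for (k in seq_len(g$d)) {
      if (G[j, k] == 0) next
      H <- H + G[j, k] * crossprod(Bs[[j]], Bu[[k]])
    }
  }
  (H + t(H)) / 2
}

#' Score and Hessian in the variance components
#'
#' For the VC structure `Gamma_i = sum_j theta_j Omega_ij` the
#' dependence part of the loglikelihood is
#' `sum_i log(1 + theta'b_i) - sum_i log(1 + theta'c_i)` with
#' `b_ij = r_i' Omega_ij r_i` and `c_ij = tr(Omega_ij)`, giving the
#' closed-form gradient and Hessian returned here.
#'
#' @inheritParams ac_loglik
#' @return list with `gradient` (length m), `hessian` (m x m), and the
#'   per-unit matrices `b` and `c`.
#' @export
ac_theta_score_hessian_vc <- function(units, beta, theta,
                                      nuis = numeric(0)) {
  stopifnot(inherits(units$struct, "ac_gamma_vc"))
  bc <- vc_bc(units, beta, nuis)
  tb <- 1 + drop(bc$b %*% theta)
  tc <- 1 + drop(bc$c %*% theta)
  grad <- colSums(bc$b / tb) - colSums(bc$c / tc)
  hess <- -crossprod(bc$b / tb) + crossprod(bc$c / tc)
  list(gradient = grad, hessian = (hess + t(hess)) / 2,
       b = bc$b, c = bc$c)
}

# per-unit b_ij = r'Omega_j r / 2 and c_ij = tr(Omega_j) / 2 for the
# VC model; the halves come from the 1/2 inside both logarithms of the
# loglikelihood, so that its dependence part is exactly
# sum_i log(1 + theta'b_i) - sum_i log(1 + theta'c_i)
vc_bc <- function(units, beta, nuis) {
  ev <- ac_eval(units, beta, rep(0, gamma_npar(units$struct, 0L)),
                nuis, score = FALSE)
  m <- length(units$struct$omega)
  b <- cc <- matrix(0, units$n, m)
  for (g in units$groups) {
    om <- vc_omegas(units$struct, g$d)
    Rg <- matrix(ev$r[g$rows], ncol = g$d)
    for (k in seq_len(m)) {
      b[g$units, k] <- rowSums((Rg %*% om[[k]]) * Rg) / 2
      cc[g$units, k] <- sum(diag(om[[k]])) / 2
    }
  }
  list(b = b, c = cc)
}

#' One MM update of the variance components
#'
#' Multiplicative minorize-maximize step
#' `theta_j <- theta_j * [sum_i b_ij/(1 + theta'b_i)] /
#'                       [sum_i c_ij/(1 + theta'c_i)]`,
#' obtained by minorizing the concave `log(1 + theta'b_i)` terms by
#' Jensen's inequality and the convex `-log(1 + theta'c_i)` terms by
#' their tangents.  The update preserves nonnegativity and never
#' decreases the loglikelihood.
#'
#' @inheritParams ac_loglik
#' @param bc optional precomputed `list(b, c)` from
#'   [ac_theta_score_hessian_vc()] (they do not depend on `theta`).
#' @return updated nonnegative `theta`.
#' @export
ac_mm_update_theta <- function(units, beta, theta, nuis = numeric(0),
                               bc = NULL) {
  if (is.null(bc)) bc <- vc_bc(units, beta, nuis)
  tb <- 1 + drop(bc$b %*% theta)
  tc <- 1 + drop(bc$c %*% theta)
  num <- colSums(bc$b / tb)
  denm <- colSums(bc$c / tc)
  upd <- ifelse(denm > 0, num / denm, 1)      # hold theta_j if degenerate
  pmax(theta * upd, 0)
}

#' One profile-Newton update of a nuisance parameter
#'
#' Newton's method on the profile loglikelihood in `log(nuisance)`
#' (log scale enforces positivity), with step halving until the
#' loglikelihood does not decrease.  The first derivative is analytic;
#' the curvature is a central finite difference of it.  Non-finite
#' curvature triggers a golden-section search on `log(nuisance)` in
#' `[-10, 10]`.
#'
#' @inheritParams ac_loglik
#' @param name which nuisance to update (`"tau2"` or `"r"`).
#' @return the updated named nuisance vector.
#' @export
ac_nuisance_step <- function(units, beta, theta, nuis,
                             name = names(nuis)[1L]) {
  l0 <- ac_loglik(units, beta, theta, nuis)
  g_of <- function(lx) {
    nu <- nuis; nu[name] <- exp(lx)
    sc <- ac_eval(units, beta, theta, nu)$score_nuis[name]
    sc * exp(lx)                               # chain rule to log scale
  }
  lx <- log(nuis[[name]])
  h <- 1e-4
  g <- g_of(lx)
  curv <- (g_of(lx + h) - g_of(lx - h)) / (2 * h)
  if (!is.finite(curv) || curv >= 0) {
    f <- function(l) {
      nu <- nuis; nu[name] <- exp(l)
      -ac_loglik(units, beta, theta, nu)
    }
    opt <- stats::optimize(f, c(-10, 10))
    nuis[name] <- exp(opt$minimum)
    return(nuis)
  }
  step <- -g / curv
  for (half in 0:20) {
    cand <- nuis; cand[name] <- exp(lx + step)
    l1 <- tryCatch(ac_loglik(units, beta, theta, cand),
                   error = function(e) -Inf)
    if (is.finite(l1) && l1 >= l0 - 1e-12) return(cand)
    step <- step / 2
  }
  nuis
}

# Fast profile maximization of the dependence block: with (beta, nuis)
# fixed the residual matrix is constant, so the theta part of the
# loglikelihood -- sum_i log(1 + r'Gr/2) - n log(1 + tr(G)/2) -- and
# its gradient cost only the per-unit quadratic forms per evaluation.
theta_profile_optimize <- function(units, beta, theta, nuis,
                                   maxit = 60L) {
  st <- units$struct
  m <- gamma_npar(st, 0L)
  if (m == 0L) return(theta)
  ev <- ac_eval(units, beta, theta, nuis, score = FALSE)
  Rg_list <- lapply(units$groups, function(g)
    matrix(ev$r[g$rows], ncol = g$d))
  lt_idx <- if (st$kind == "unstr") {
    ij <- which(lower.tri(diag(st$d), diag = TRUE), arr.ind = TRUE)
    ij[order(ij[, 2L], ij[, 1L]), , drop = FALSE]
  }
  part <- function(th) {
    val <- 0
    for (gi in seq_along(units$groups)) {
      g <- units$groups[[gi]]
      G <- gamma_materialize(st, th, g$d)
      Rg <- Rg_list[[gi]]
      quad <- rowSums((Rg %*% G) * Rg)
      val <- val + sum(log1p(quad / 2)) -
        length(g$units) * log1p(sum(diag(G)) / 2)
    }
    val
  }
  fn <- function(psi) {
    th <- tryCatch(gamma_from_free(st, psi), error = function(e) NULL)
    if (is.null(th)) return(1e12)
    v <- part(th)
    if (is.finite(v)) -v else 1e12
  }
  gr <- function(psi) {
    th <- gamma_from_free(st, psi)
    jac <- gamma_free_jac(st, psi)
    gvec <- numeric(m)
    for (gi in seq_along(units$groups)) {
      g <- units$groups[[gi]]; Rg <- Rg_list[[gi]]
      G <- gamma_materialize(st, th, g$d)
      den <- 1 + rowSums((Rg %*% G) * Rg) / 2
      cn <- 1 + sum(diag(G)) / 2
      ng <- length(g$units)
      if (st$kind == "unstr") {
        L <- unvech(th, st$d)
        RL <- Rg %*% L
        dquad <- 2 * Rg[, lt_idx[, 1L], drop = FALSE] *
          RL[, lt_idx[, 2L], drop = FALSE]
        dtr <- 2 * L[lt_idx]
        gvec <- gvec + colSums(dquad / (2 * den)) - ng * dtr / (2 * cn)
      } else {
        dG <- gamma_deriv(st, th, g$d)
        for (k in seq_len(m)) {
          dq <- rowSums((Rg %*% dG[[k]]) * Rg)
          gvec[k] <- gvec[k] + sum(dq / (2 * den)) -
            ng * sum(diag(dG[[k]])) / (2 * cn)
        }
      }
    }
    -(gvec * jac)
  }
  psi0 <- gamma_to_free(st, theta)
  opt <- tryCatch(stats::optim(psi0, fn, gr, method = "BFGS",
                               control = list(maxit = maxit,
                                              reltol = 1e-13)),
                  error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value) && opt$value <= -part(theta))
    gamma_from_free(st, opt$par)
  else theta
}

# cached-score closure: with (beta, nuis) fixed, the family-level
# quantities (mu, residuals, base scores) are constant, so the joint
# score at a new theta costs only the per-unit quadratic forms
make_theta_score <- function(units, ev) {
  st <- units$struct
  m <- gamma_npar(st, 0L)
  Rg_list <- lapply(units$groups, function(g)
    matrix(ev$r[g$rows], ncol = g$d))
  lt_idx <- if (st$kind == "unstr") {
    ij <- which(lower.tri(diag(st$d), diag = TRUE), arr.ind = TRUE)
    ij[order(ij[, 2L], ij[, 1L]), , drop = FALSE]
  }
  nn <- names(ev$nuis_template %||% NULL)
  function(theta) {
    Avec <- numeric(length(units$y))
    den_u <- cn_u <- numeric(units$n)
    dquad_u <- dtr_u <- matrix(0, units$n, m)
    for (gi in seq_along(units$groups)) {
      g <- units$groups[[gi]]
      G <- tryCatch(gamma_materialize(st, theta, g$d),
                    error = function(e) NULL)
      if (is.null(G)) return(NULL)
      Rg <- Rg_list[[gi]]
      Ag <- Rg %*% G
      Avec[g$rows] <- Ag
      den_u[g$units] <- 1 + rowSums(Ag * Rg) / 2
      cn_u[g$units] <- 1 + sum(diag(G)) / 2
      if (m > 0L) {
        if (st$kind == "unstr") {
          L <- unvech(theta, st$d)
          RL <- Rg %*% L
          dquad_u[g$units, ] <- 2 * Rg[, lt_idx[, 1L], drop = FALSE] *
            RL[, lt_idx[, 2L], drop = FALSE]
          dtr_u[g$units, ] <- matrix(2 * L[lt_idx], length(g$units), m,
                                     byrow = TRUE)
        } else {
          dG <- gamma_deriv(st, theta, g$d)
          for (k in seq_len(m)) {
            dquad_u[g$units, k] <- rowSums((Rg %*% dG[[k]]) * Rg)
            dtr_u[g$units, k] <- sum(diag(dG[[k]]))
          }
        }
      }
    }
    den_row <- den_u[units$unit]
    w <- ev$dlf + Avec * ev$drdeta / den_row
    sb <- drop(crossprod(units$X, w))
    sth <- if (m > 0L)
      colSums(dquad_u / (2 * den_u)) - colSums(dtr_u / (2 * cn_u))
    else numeric(0)
    snu <- numeric(length(ev$score_nuis))
    if (length(snu)) {
      for (i in seq_along(snu)) {
        drdnu <- ev$drdnu_list[[i]]
        snu[i] <- ev$dlf_nu_sums[i] +
          sum(drop(rowsum(Avec * drdnu, units$unit)) / den_u)
      }
    }
    c(sb, sth, snu)
  }
}

# Joint Newton ascent over (beta, theta, nuisance): analytic NSD
# curvature on the beta block, finite-difference columns of the
# analytic joint score for the dependence and nuisance parameters
# (capturing the cross-coupling that makes pure block ascent slow).
# indices (within the theta block, offset by P) of dependence
# parameters bounded below by zero
lb_indices <- function(struct, P) {
  P + switch(struct$kind,
    vc = seq_along(struct$omega), ar1 = 1L, cs = 1L,
    unstr = {
      ij <- which(lower.tri(diag(struct$d), diag = TRUE),
                  arr.ind = TRUE)
      ij <- ij[order(ij[, 2L], ij[, 1L]), , drop = FALSE]
      which(ij[, 1L] == ij[, 2L])
    },
    integer(0))
}

# KKT residual on the free scale: the gradient sup-norm with
# boundary-active coordinates (value at zero, gradient pointing
# outward) removed
kkt_measure <- function(units, beta, theta, nuis) {
  ev <- ac_eval(units, beta, theta, nuis)
  g_nat <- c(ev$score_beta, ev$score_theta, ev$score_nuis)
  P <- units$P; m <- gamma_npar(units$struct, 0L)
  psi_th <- gamma_to_free(units$struct, theta)
  jac <- c(rep(1, P), gamma_free_jac(units$struct, psi_th),
           if (length(nuis)) nuis)
  g_free <- g_nat * jac
  lb <- lb_indices(units$struct, P)
  active <- lb[c(theta, nuis)[lb - P] <= 1e-5 & g_nat[lb] < 0]
  if (length(active)) g_free[active] <- 0
  list(norm = max(abs(g_free)), active = active - P)
}

joint_newton <- function(units, beta, theta, nuis, maxit = 10L,
                         gtol = 1e-5) {
  P <- units$P; m <- length(theta); nn <- length(nuis)
  K <- P + m + nn
  st <- units$struct
  # theta coordinates bounded below by zero (candidates for an active
  # constraint at the solution)
  lb <- lb_indices(st, P)
  ll <- ac_loglik(units, beta, theta, nuis)
  gnorm <- Inf
  for (it in seq_len(maxit)) {
    ev <- ac_eval(units, beta, theta, nuis)
    # stash pieces the cached scorer needs
    if (nn) {
      ev$drdnu_list <- lapply(names(nuis), function(nm) {
        fam <- if (nm == "tau2") "gaussian" else "nbinom"
        idx <- units$fam_row == fam
        v <- numeric(length(units$y))
        v[idx] <- -ev$r[idx] * ev$dv_nu[idx] / (2 * ev$s2[idx])
        v
      })
      ev$dlf_nu_sums <- vapply(names(nuis), function(nm) {
        fam <- if (nm == "tau2") "gaussian" else "nbinom"
        sum(ev$dlf_nu[units$fam_row == fam])
      }, 0)
    }
    g <- c(ev$score_beta, ev$score_theta, ev$score_nuis)
    # freeze boundary coordinates whose gradient points outward; the
    # KKT residual ignores them
    active <- lb[c(theta, nuis)[lb - P] <= 1e-5 & g[lb] < 0]
    free_ix <- setdiff(seq_len(K), active)
    gnorm <- max(abs(g[free_ix]), 0)
    if (gnorm < gtol) break
    # exact observed curvature on beta gives quadratic local
    # convergence; finite-difference columns of the analytic score
    # supply the dependence/nuisance blocks and their cross-coupling.
    # The assembled matrix is reused over a few iterations.
    build_cross <- function() {
      H <- matrix(0, K, K)
      if (m > 0L) {
        scorer <- make_theta_score(units, ev)
        for (k in seq_len(m)) {
          h <- max(abs(theta[k]), 1e-2) * 1e-6
          gp <- scorer(theta + h * (seq_len(m) == k))
          gm <- scorer(theta - h * (seq_len(m) == k))
          col <- if (!is.null(gp) && !is.null(gm)) (gp - gm) / (2 * h)
          else if (!is.null(gp)) (gp - g) / h
          else NULL
          if (is.null(col)) col <- numeric(K)
          H[, P + k] <- col
        }
      }
      if (nn) for (i in seq_len(nn)) {
        h <- max(abs(nuis[i]), 1e-2) * 1e-5
        pert <- function(s) {
          nu <- nuis; nu[i] <- nu[i] + s * h
          e2 <- ac_eval(units, beta, theta, nu)
          c(e2$score_beta, e2$score_theta, e2$score_nuis)
        }
        H[, P + m + i] <- (pert(1) - pert(-1)) / (2 * h)
      }
      # mirror the FD columns into the corresponding rows, average
      if (K > P)
        H[-seq_len(P), seq_len(P)] <- t(H[seq_len(P), -seq_len(P),
                                          drop = FALSE])
      (H + t(H)) / 2
    }
    H <- build_cross()
    H[seq_len(P), seq_len(P)] <-
      ac_hessian_beta(units, beta, theta, nuis, exact = TRUE)
    scale_par <- 1 + max(abs(c(beta, theta, nuis)))
    line_search <- function(step) {
      # cap an exploding (ill-conditioned) step before backtracking
      if (max(abs(step)) > 5 * scale_par)
        step <- step * 5 * scale_par / max(abs(step))
      slope <- sum(g * step)
      if (!is.finite(slope) || slope <= 0) return(NULL)
      for (half in 0:40) {
        cand <- project_params(units, beta + step[seq_len(P)],
                               theta + step[P + seq_len(m)],
                               nuis + step[P + m + seq_len(nn)])
        llc <- tryCatch(ac_loglik(units, cand$beta, cand$theta,
                                  cand$nuis),
                        error = function(e) -Inf)
        # Armijo sufficient increase keeps the search off plateaus
        if (is.finite(llc) && llc >= ll + 1e-4 * slope) {
          cand$loglik <- llc
          return(cand)
        }
        step <- step / 2
        slope <- slope / 2
      }
      NULL
    }
    try_step <- function(Hm) {
      Hf <- Hm[free_ix, free_ix, drop = FALSE]
      sf <- tryCatch(solve(-Hf + diag(1e-8 * (1 + max(abs(diag(Hf)))),
                                      length(free_ix)), g[free_ix]),
                     error = function(e) NULL)
      if (is.null(sf) || !all(is.finite(sf))) return(NULL)
      step <- numeric(K)
      step[free_ix] <- sf
      line_search(step)
    }
    cand <- try_step(H)
    if (is.null(cand)) {
      H[seq_len(P), seq_len(P)] <-
        ac_hessian_beta(units, beta, theta, nuis, exact = FALSE)
      cand <- try_step(H)
    }
    if (is.null(cand)) {
      # steepest-ascent fallback when both curvature models fail
      step <- numeric(K)
      step[free_ix] <- g[free_ix] / max(abs(g[free_ix])) * 0.1
      cand <- line_search(step)
    }
    if (is.null(cand)) break
    beta <- cand$beta; theta <- cand$theta; nuis <- cand$nuis
    ll <- cand$loglik
  }
  list(beta = beta, theta = theta, nuis = nuis, loglik = ll,
       gnorm = gnorm, iters = it)
}

# project a candidate parameter point back into the admissible set
project_params <- function(units, beta, theta, nuis) {
  st <- units$struct
  theta <- switch(st$kind,
    vc = pmax(theta, 0),
    ar1 = c(max(theta[1L], 0), max(min(theta[2L], 0.999), -0.999)),
    cs = {
      lo <- cs_rho_min(st$d_max %||% 2L)
      c(max(theta[1L], 0), max(min(theta[2L], 1), lo))
    },
    unstr = {
      L <- unvech(theta, st$d)
      diag(L) <- pmax(diag(L), 0)
      vech(L)
    },
    theta)
  if (length(nuis)) nuis <- pmax(nuis, 1e-10)
  list(beta = beta, theta = theta, nuis = nuis)
}

# joint parameter vector helpers: phi = (beta, theta, nuis) on the
# natural scale; psi = transformed free scale used by quasi-Newton
pack_free <- function(units, beta, theta, nuis)
  c(beta, gamma_to_free(units$struct, theta),
    if (length(nuis)) log(nuis))

unpack_free <- function(units, psi) {
  P <- units$P
  m <- gamma_npar(units$struct, 0L)
  nn <- nuis_names(units)
  theta <- gamma_from_free(units$struct, psi[P + seq_len(m)])
  nuis <- if (length(nn))
    stats::setNames(exp(psi[P + m + seq_along(nn)]), nn)
  else numeric(0)
  list(beta = psi[seq_len(P)], theta = theta, nuis = nuis)
}

# gradient of the loglikelihood on the free scale
free_grad <- function(units, psi) {
  pp <- unpack_free(units, psi)
  ev <- ac_eval(units, pp$beta, pp$theta, pp$nuis)
  m <- gamma_npar(units$struct, 0L)
  jac <- gamma_free_jac(units$struct,
                        psi[units$P + seq_len(m)])
  c(ev$score_beta, ev$score_theta * jac,
    if (length(pp$nuis)) ev$score_nuis * pp$nuis)
}

free_negloglik <- function(units, psi) {
  pp <- unpack_free(units, psi)
  ll <- tryCatch(ac_loglik(units, pp$beta, pp$theta, pp$nuis),
                 error = function(e) -Inf)
  if (!is.finite(ll)) 1e12 else -ll
}

#' Per-unit joint scores
#'
#' Score contributions of each sampling unit to the full parameter
#' vector `(beta, theta, nuisance)` on the natural scale; their outer
#' products form the meat of the sandwich covariance.
#'
#' @inheritParams ac_loglik
#' @return an `n x K` matrix, one row per unit.
#' @export
ac_unit_scores <- function(units, beta, theta, nuis = numeric(0)) {
  ev <- ac_eval(units, beta, theta, nuis)
  den_row <- ev$den[units$unit]
  Sb <- rowsum(ev$w_beta * units$X, units$unit)
  out <- Sb
  m <- gamma_npar(units$struct, 0L)
  if (m > 0L)
    out <- cbind(out, ev$dquad_u / (2 * ev$den) -
                   ev$dtr_u / (2 * ev$cnorm))
  for (nm in names(nuis)) {
    fam <- if (nm == "tau2") "gaussian" else "nbinom"
    idx <- units$fam_row == fam
    drdnu <- numeric(length(units$y))
    drdnu[idx] <- -ev$r[idx] * ev$dv_nu[idx] / (2 * ev$s2[idx])
    per_u <- drop(rowsum(ev$dlf_nu * idx, units$unit)) +
      drop(rowsum(ev$A * drdnu, units$unit)) / ev$den
    out <- cbind(out, per_u)
  }
  colnames(out) <- c(colnames(units$X) %||% paste0("beta", seq_len(units$P)),
                     gamma_par_names(units$struct, 0L), names(nuis))
  out
}

# total joint score on the natural scale (for FD Hessian in sandwich)
joint_score_natural <- function(units, beta, theta, nuis)
  colSums(ac_unit_scores(units, beta, theta, nuis))

#' Sandwich covariance of a fitted model
#'
#' Robust covariance `A^{-1} B A^{-1}` with `A` the negative observed
#' joint Hessian (a central finite difference of the analytic joint
#' score) and `B` the sum of per-unit score outer products, both over
#' the full `(beta, theta, nuisance)` block on the natural scale.
#' A singular `A` falls back to an eigenvalue pseudo-inverse and sets
#' the `pseudo` flag.
#'
#' @inheritParams ac_loglik
#' @return list with `vcov`, `A`, `B`, and logical `pseudo`.
#' @export
ac_sandwich <- function(units, beta, theta, nuis = numeric(0)) {
  phi <- c(beta, theta, nuis)
  K <- length(phi)
  P <- units$P; m <- length(theta)
  score_at <- function(p) {
    th <- p[P + seq_len(m)]
    th <- pmax(th, if (units$struct$kind == "vc") 0 else -Inf)
    joint_score_natural(units, p[seq_len(P)], th,
                        stats::setNames(p[P + m + seq_along(nuis)],
                                        names(nuis)))
  }
  A <- matrix(0, K, K)
  h <- pmax(abs(phi), 1) * 1e-5
  for (k in seq_len(K)) {
    e <- numeric(K); e[k] <- h[k]
    # one-sided at a nonnegativity boundary, central otherwise
    lowerable <- !(units$struct$kind == "vc" && k > P && k <= P + m &&
                     phi[k] < h[k])
    A[, k] <- if (lowerable)
      -(score_at(phi + e) - score_at(phi - e)) / (2 * h[k])
    else
      -(score_at(phi + e) - score_at(phi)) / h[k]
  }
  A <- (A + t(A)) / 2
  S <- ac_unit_scores(units, beta, theta, nuis)
  B <- crossprod(S)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  pseudo <- is.null(Ainv)
  if (pseudo) {
    eg <- eigen(A, symmetric = TRUE)
    keep <- abs(eg$values) > 1e-10 * max(abs(eg$values))
    Ainv <- eg$vectors[, keep, drop = FALSE] %*%
      (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
  }
  V <- Ainv %*% B %*% t(Ainv)
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(B) <- dimnames(A) <-
    list(colnames(S), colnames(S))
  list(vcov = V, A = A, B = B, pseudo = pseudo)
}
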