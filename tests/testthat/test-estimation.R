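test_that("the loglikelihood sums per-unit tilted log densities", {
  units <- make_pois_units(n = 50, d = 3, seed = 11)
  beta <- c(0.1, -0.05, 0.12); theta <- 0.2
  ll <- ac_loglik(units, beta, theta)
  G <- gamma_materialize(units$struct, theta, 3)
  by_unit <- vapply(seq_len(units$n), function(i) {
    rows <- which(units$unit == i)
    mu <- exp(drop(units$X[rows, ] %*% beta))
    dist <- ac_dist(ac_margin("poisson"), mu = mu, Gamma = G)
    dac(units$y[rows], dist, log = TRUE)
  }, 0)
  expect_equal(ll, sum(by_unit), tolerance = 1e-10)
  # Gamma = 0, Gaussian base: ordinary least-squares loglikelihood
  set.seed(12)
  n <- 120; x <- rnorm(n); y <- 0.4 + 0.8 * x + rnorm(n)
  ug <- ac_units(y, cbind(1, x), seq_len(n), ac_margin("gaussian"),
                 gamma_fixed(matrix(0, 1, 1)))
  b <- c(0.4, 0.8)
  expect_equal(ac_loglik(ug, b, numeric(0), c(tau2 = 1.3)),
               sum(dnorm(y, cbind(1, x) %*% b, sqrt(1.3), log = TRUE)))
})

test_that("scores match finite differences for every parameter block", {
  cases <- list(
    list(units = make_pois_units(n = 20, d = 4, seed = 21),
         beta = c(0.1, -0.1, 0.05), theta = 0.25, nuis = numeric(0)),
    list(units = sim_longitudinal("I", n = 25, d = 3,
                                  family = "nbinom", theta = 0.1,
                                  p = 2, r = 8, seed = 22)$units,
         beta = c(0.1, 0.1, -0.1), theta = 0.15, nuis = c(r = 6)))
  for (cs in cases) {
    sc <- ac_score(cs$units, cs$beta, cs$theta, cs$nuis)
    expect_equal(unname(sc$beta),
                 fd_grad(function(b) ac_loglik(cs$units, b, cs$theta,
                                               cs$nuis), cs$beta),
                 tolerance = 1e-6)
    expect_equal(sc$theta,
                 fd_grad(function(t) ac_loglik(cs$units, cs$beta, t,
                                               cs$nuis), cs$theta),
                 tolerance = 1e-6)
    if (length(cs$nuis))
      expect_equal(unname(sc$nuis),
                   fd_grad(function(nu) ac_loglik(
                     cs$units, cs$beta, cs$theta,
                     setNames(nu, names(cs$nuis))), cs$nuis),
                   tolerance = 1e-5)
  }
  # Gaussian identity link: residual Jacobian is -X/sigma exactly, so
  # with Gamma = 0 the score is the classical least-squares score
  set.seed(23)
  n <- 40; X <- cbind(1, rnorm(n)); y <- rnorm(n)
  ug <- ac_units(y, X, seq_len(n), ac_margin("gaussian"),
                 gamma_fixed(matrix(0, 1, 1)))
  sc <- ac_score(ug, c(0.2, 0.1), numeric(0), c(tau2 = 2))
  expect_equal(unname(sc$beta),
               drop(crossprod(X, y - X %*% c(0.2, 0.1))) / 2)
})

test_that("exact Hessian matches the score Jacobian and known forms", {
  units <- sim_longitudinal("I", n = 25, d = 3, family = "nbinom",
                            theta = 0.12, p = 2, r = 9,
                            seed = 31)$units
  beta <- c(0.08, -0.1, 0.1); theta <- 0.2; nuis <- c(r = 7)
  H <- ac_hessian_beta(units, beta, theta, nuis, exact = TRUE)
  expect_equal(H, t(H), tolerance = 1e-10)
  fdH <- fd_jac(function(b)
    ac_score(units, b, theta, nuis, "beta")$beta, beta, h = 1e-5)
  expect_lt(max(abs(H - fdH)), 1e-5 * (1 + max(abs(fdH))))
  # Gaussian identity, Gamma = 0: -X'X / tau2
  set.seed(32)
  n <- 30; X <- cbind(1, rnorm(n)); y <- rnorm(n)
  ug <- ac_units(y, X, seq_len(n), ac_margin("gaussian"),
                 gamma_fixed(matrix(0, 1, 1)))
  expect_equal(ac_hessian_beta(ug, c(0, 0), numeric(0), c(tau2 = 1.7),
                               exact = TRUE),
               -crossprod(X) / 1.7, tolerance = 1e-10)
})

test_that("the approximate Hessian is negative semidefinite and ascends", {
  set.seed(41)
  units <- make_pois_units(n = 40, d = 4, seed = 41)
  # NSD at random parameter points
  for (i in 1:100) {
    beta <- runif(3, -0.4, 0.4); theta <- runif(1, 0, 0.5)
    Ha <- ac_hessian_beta(units, beta, theta, exact = FALSE)
    ev <- eigen(Ha, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(ev), 1e-10 * max(abs(ev)))
  }
  # with Gamma = 0 it is minus the expected base information
  u0 <- ac_units(units$y, units$X, units$unit, ac_margin("poisson"),
                 gamma_vc("intercept"))
  beta <- c(0.1, 0, -0.1)
  mu <- exp(drop(units$X %*% beta))
  expect_equal(ac_hessian_beta(u0, beta, 0, exact = FALSE),
               -crossprod(units$X * mu, units$X),
               tolerance = 1e-10)
  # Newton steps with step halving increase the loglikelihood
  for (rep in 1:20) {
    beta <- runif(3, -0.3, 0.3); theta <- runif(1, 0.05, 0.3)
    ll0 <- ac_loglik(units, beta, theta)
    sc <- ac_score(units, beta, theta, which = "beta")$beta
    Ha <- ac_hessian_beta(units, beta, theta, exact = FALSE)
    step <- solve(-Ha + diag(1e-8, 3), sc)
    ll1 <- -Inf
    for (h in 0:20) {
      ll1 <- tryCatch(ac_loglik(units, beta + step, theta),
                      error = function(e) -Inf)
      if (is.finite(ll1) && ll1 >= ll0) break
      step <- step / 2
    }
    expect_gte(ll1, ll0)
  }
})

test_that("variance-component score and Hessian have their closed forms", {
  units <- make_pois_units(n = 50, d = 4, seed = 51)
  beta <- c(0.1, -0.05, 0.08)
  sh <- ac_theta_score_hessian_vc(units, beta, 0.2)
  expect_equal(sh$gradient,
               fd_grad(function(t) ac_loglik(units, beta, t), 0.2),
               tolerance = 1e-6)
  expect_equal(drop(sh$hessian),
               fd_grad(function(t)
                 ac_theta_score_hessian_vc(units, beta, t)$gradient,
                 0.2),
               tolerance = 1e-5)
  # theta = 0: gradient is sum of (quadratic form - trace)
  sh0 <- ac_theta_score_hessian_vc(units, beta, 0)
  expect_equal(sh0$gradient, sum(sh0$b) - sum(sh0$c))
})

test_that("the MM update is a monotone ascent with the right fixed points", {
  units <- make_pois_units(n = 400, d = 5, theta = 0.1, seed = 61)
  beta <- c(0.1, -0.05, 0.08)
  theta <- 0.5
  lls <- numeric(200)
  for (it in 1:200) {
    theta <- ac_mm_update_theta(units, beta, theta)
    lls[it] <- ac_loglik(units, beta, theta)
  }
  expect_true(all(diff(lls) > -1e-9))
  # converged point matches direct 1-D maximization
  opt <- optimize(function(t) ac_loglik(units, beta, t), c(0, 2),
                  maximum = TRUE, tol = 1e-10)
  expect_equal(theta, opt$maximum, tolerance = 1e-6)
  # stationary point is a fixed point
  expect_equal(ac_mm_update_theta(units, beta, theta), theta,
               tolerance = 1e-6)
})

test_that("fitting with Gamma constrained to zero recovers the GLM", {
  set.seed(71)
  n <- 300; x <- rnorm(n)
  y <- rpois(n, exp(0.3 + 0.4 * x))
  u <- ac_units(y, cbind(1, x), seq_len(n), ac_margin("poisson"),
                gamma_fixed(matrix(0, 1, 1)))
  fit <- acm_fit(u)
  ref <- glm(y ~ x, family = poisson())
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("fits are invariant to permuting the unit order", {
  sim <- sim_longitudinal("I", n = 150, d = 3, family = "poisson",
                          theta = 0.12, p = 2, seed = 81)
  f1 <- acm_fit(sim$units, sandwich = FALSE)
  perm <- sample(150)
  ord <- order(match(sim$data$id, perm))
  d2 <- sim$data[ord, ]
  X2 <- cbind(1, as.matrix(d2[, c("x1", "x2")]))
  u2 <- ac_units(d2$y, X2, d2$id, ac_margin("poisson"),
                 gamma_vc("intercept"))
  f2 <- acm_fit(u2, sandwich = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(unname(f1$beta), unname(f2$beta), tolerance = 1e-4)
})

test_that("block ascent is monotone and the trace records it", {
  sim <- sim_longitudinal("I", n = 200, d = 4, family = "poisson",
                          theta = 0.15, p = 2, seed = 91)
  fit <- acm_fit(sim$units, sandwich = FALSE)
  expect_true(all(diff(fit$trace$loglik) > -1e-8))
  expect_true(fit$converged)
})

test_that("sandwich matches the model covariance when correctly specified", {
  set.seed(101)
  n <- 3000; x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  u <- ac_units(y, cbind(1, x), seq_len(n), ac_margin("gaussian"),
                gamma_fixed(matrix(0, 1, 1)))
  fit <- acm_fit(u)
  se_sand <- sqrt(diag(fit$vcov))[1:2]
  se_model <- sqrt(diag(vcov(lm(y ~ x))))
  expect_true(all(se_sand / se_model > 0.8 & se_sand / se_model < 1.25))
  # per-unit score matrix: each row is one unit's contribution
  S <- ac_unit_scores(u, fit$beta, fit$theta, fit$nuis)
  expect_equal(colSums(S),
               unname(c(ac_score(u, fit$beta, fit$theta,
                                 fit$nuis)$beta,
                        fit$nuis * 0 + ac_score(u, fit$beta, fit$theta,
                                                fit$nuis)$nuis)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_lte(qr(tcrossprod(S[1, ]))$rank, ncol(S))
})

test_that("a variance component on the boundary is reported as zero", {
  # independent data: the MLE of theta sits at the nonnegativity bound
  sim <- sim_longitudinal("I", n = 600, d = 3, family = "poisson",
                          theta = 0, p = 2, seed = 111)
  fit <- acm_fit(sim$units)
  expect_lte(fit$theta, 0.02)
  if (fit$theta == 0) expect_true(any(fit$boundary))
  # an SE is still reported from the unconstrained sandwich
  expect_true(all(is.finite(sqrt(pmax(diag(fit$vcov), 0)))))
})
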