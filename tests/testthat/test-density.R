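test_that("zero Gamma reduces the joint density to the base product", {
  dist <- ac_dist(ac_margin("poisson"), mu = c(2, 3),
                  Gamma = matrix(0, 2, 2))
  y <- cbind(0:6, c(0, 2, 4, 1, 3, 5, 2))
  expect_equal(dac(y, dist, log = TRUE),
               margin_logpdf(ac_margin("poisson"), y[, 1], 2) +
                 margin_logpdf(ac_margin("poisson"), y[, 2], 3))
  m <- ac_moments(dist)
  expect_equal(m$mean, c(2, 3))
  expect_equal(m$cov, diag(c(2, 3)))
  expect_equal(m$corr, diag(2))
})

test_that("the density integrates to one for mixed margins up to d = 3", {
  dists <- list(
    ac_dist(ac_margin("poisson"), mu = c(2, 3), Gamma = 0.2 * diag(2)),
    ac_dist(list(ac_margin("gaussian", tau2 = 0.7),
                 ac_margin("gaussian", tau2 = 1.5)),
            mu = c(-1, 2), Gamma = matrix(c(.3, .2, .2, .4), 2)),
    ac_dist(list(ac_margin("poisson"), ac_margin("bernoulli"),
                 ac_margin("gaussian", tau2 = 0.5)),
            mu = c(2, 0.4, 1),
            Gamma = matrix(c(.2, .1, .05, .1, .3, .1, .05, .1, .25),
                           3)),
    ac_dist(list(ac_margin("nbinom", r = 5), ac_margin("bernoulli")),
            mu = c(3, 0.3), Gamma = matrix(c(.4, -.1, -.1, .2), 2)))
  for (dist in dists)
    expect_equal(oracle_mass(dist), 1, tolerance = 1e-6)
})

test_that("exact moments match the enumeration oracle", {
  dist <- ac_dist(list(ac_margin("poisson"), ac_margin("bernoulli")),
                  mu = c(2, 0.4),
                  Gamma = matrix(c(0.1, 0.05, 0.05, 0.1), 2))
  om <- oracle_moments(dist)
  m <- ac_moments(dist)
  expect_equal(m$mean, unname(om$mean), tolerance = 1e-8)
  expect_equal(m$cov, unname(om$cov), tolerance = 1e-8)
  # Gaussian margins have zero skewness, so the mean is exactly mu
  dg <- ac_dist(ac_margin("gaussian", tau2 = 1), mu = c(1, -2),
                Gamma = matrix(c(.5, .3, .3, .5), 2))
  expect_equal(ac_moments(dg)$mean, c(1, -2))
})

test_that("small-Gamma expansions approach the exact moments", {
  # error of the truncated formulas is O(||Gamma||^2): the scaled error
  # must stay bounded as Gamma -> 0
  ratios <- sapply(c(0.2, 0.1, 0.05, 0.025), function(gam) {
    dist <- ac_dist(ac_margin("poisson"), mu = c(2, 3),
                    Gamma = gam * diag(2))
    ex <- ac_moments(dist); ap <- ac_moments(dist, expand = TRUE)
    max(abs(ex$mean - ap$mean), abs(ex$cov - ap$cov)) / gam^2
  })
  expect_lt(max(ratios) / min(ratios), 10)
})

test_that("variance inflation matches the exact diagonal formula", {
  for (gam in c(0.05, 0.1, 0.2, 0.3)) {
    dist <- ac_dist(ac_margin("poisson"), mu = c(2, 3),
                    Gamma = gam * diag(2))
    om <- oracle_moments(dist)
    m <- ac_moments(dist)
    expect_equal(diag(m$cov), unname(diag(om$cov)), tolerance = 1e-8)
    # kurtosis >= 1 for every base, so the second moment about mu is
    # inflated relative to the base variance
    cc <- 1 + gam
    second_mom <- diag(om$cov) + (om$mean - dist$mu)^2
    expect_gte(second_mom[1] * cc, 2)
    expect_gte(second_mom[2] * cc, 3)
  }
})

test_that("the tilt has unit mean under the independent base product", {
  # E_base[1 + r' Gamma r / 2] = 1 + tr(Gamma)/2, checked by Monte Carlo
  set.seed(10)
  n <- 1e6
  mu <- c(2, 0.4); G <- matrix(c(0.3, 0.1, 0.1, 0.2), 2)
  y1 <- rpois(n, mu[1]); y2 <- rbinom(n, 1, mu[2])
  r1 <- (y1 - mu[1]) / sqrt(mu[1])
  r2 <- (y2 - mu[2]) / sqrt(mu[2] * (1 - mu[2]))
  tilt <- 1 + (G[1, 1] * r1^2 + 2 * G[1, 2] * r1 * r2 +
                 G[2, 2] * r2^2) / 2
  se <- sd(tilt) / sqrt(n)
  expect_lt(abs(mean(tilt) - (1 + sum(diag(G)) / 2)), 3 * se)
})

test_that("marginals equal the summed joint", {
  G3 <- matrix(c(.2, .1, .05, .1, .25, .08, .05, .08, .15), 3)
  dist <- ac_dist(ac_margin("poisson"), mu = c(2, 3, 1.5), Gamma = G3)
  marg <- ac_marginal(dist, c(1, 2))
  k3 <- 0:30
  for (y1 in 0:8) for (y2 in c(0, 3, 6)) {
    joint_sum <- sum(dac(cbind(y1, y2, k3), dist))
    expect_equal(dac(c(y1, y2), marg), joint_sum, tolerance = 1e-10)
  }
  # S = {1..d} gives back the joint; Gamma = 0 gives the bare margin
  full <- ac_marginal(dist, 1:3)
  y <- cbind(1, 2, 0)
  expect_equal(dac(y, full), dac(y, dist))
  d0 <- ac_dist(ac_margin("poisson"), mu = c(2, 3),
                Gamma = matrix(0, 2, 2))
  expect_equal(dac(matrix(0:8), ac_marginal(d0, 1)),
               dpois(0:8, 2))
  expect_error(ac_marginal(dist, integer(0)), "nonempty")
  # a marginal integrates to one
  expect_equal(oracle_mass(marg), 1, tolerance = 1e-8)
})

test_that("conditionals equal joint over marginal", {
  dist <- ac_dist(ac_margin("poisson"), mu = c(2, 3),
                  Gamma = matrix(c(.2, .12, .12, .3), 2))
  for (yT in c(0, 2, 5)) {
    cond <- ac_conditional(dist, T = 2, y_T = yT)
    ratio <- dac(cbind(0:20, yT), dist) /
      dac(matrix(yT), ac_marginal(dist, 2))
    expect_equal(dac(matrix(0:20), cond), ratio, tolerance = 1e-12)
    expect_equal(sum(dac(matrix(0:40), cond)), 1, tolerance = 1e-10)
  }
  # independence: conditional is the bare margin
  d0 <- ac_dist(ac_margin("poisson"), mu = c(2, 3),
                Gamma = matrix(0, 2, 2))
  expect_equal(dac(matrix(0:8), ac_conditional(d0, 2, 4)),
               dpois(0:8, 2))
})

test_that("conditional and marginal means agree to second order", {
  # difference scaled by ||Gamma||^2 stays bounded as Gamma shrinks
  ks <- sapply(c(0.05, 0.1, 0.2), function(gam) {
    G <- gam * matrix(c(1, .5, .5, 1), 2)
    dist <- ac_dist(ac_margin("poisson"), mu = c(2, 3), Gamma = G)
    cond <- ac_conditional(dist, T = 2, y_T = 4)
    k <- 0:40
    cmean <- sum(k * dac(matrix(k), cond))
    mmean <- sum(k * dac(matrix(k), ac_marginal(dist, 1)))
    abs(cmean - mmean) / norm(G, "2")^2
  })
  expect_lt(max(ks) / min(ks), 10)
})
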