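test_that("stage densities reduce correctly and obey the chain rule", {
  G <- matrix(c(.2, .1, .06, .1, .25, .08, .06, .08, .15), 3)
  dist <- ac_dist(ac_margin("poisson"), mu = c(2, 3, 1.5), Gamma = G)
  # i = 1 stage is the single-component marginal
  st1 <- ac_stage_density(dist, 1)
  expect_equal(dac(matrix(0:15), st1),
               dac(matrix(0:15), ac_marginal(dist, 1)),
               tolerance = 1e-12)
  # Gamma = 0: every stage is the bare margin
  d0 <- ac_dist(ac_margin("poisson"), mu = c(2, 3),
                Gamma = matrix(0, 2, 2))
  expect_equal(dac(matrix(0:10), ac_stage_density(d0, 2, r_prev = 1.3)),
               dpois(0:10, 3))
  # chain rule: product of stage densities equals the joint pointwise
  sds <- sapply(1:3, function(k)
    sqrt(margin_moments(ac_margin("poisson"), dist$mu[k])$var))
  for (trial in 1:20) {
    y <- c(sample(0:6, 1), sample(0:8, 1), sample(0:5, 1))
    r <- (y - dist$mu) / sds
    lp <- dac(matrix(0:0 + y[1], 1), ac_stage_density(dist, 1),
              log = TRUE) +
      dac(matrix(y[2]), ac_stage_density(dist, 2, r[1]), log = TRUE) +
      dac(matrix(y[3]), ac_stage_density(dist, 3, r[1:2]), log = TRUE)
    expect_equal(lp, dac(y, dist, log = TRUE), tolerance = 1e-10)
  }
})

test_that("mode-first discrete inversion walks the reordered partition", {
  # two-point pmf (p0, p1) = (0.3, 0.7), mode hint 1: order is p1, p0
  expect_equal(ac_draw_discrete(c(0.3, 0.7), nu = 1, u = 0.5), 1)
  expect_equal(ac_draw_discrete(c(0.3, 0.7), nu = 1, u = 0.8), 0)
  # degenerate pmf always returns its atom
  for (u in c(0, 0.3, 0.99))
    expect_equal(ac_draw_discrete(c(0, 0, 1, 0), nu = 2, u = u), 2)
  # identical distribution to natural-order inversion: each atom k
  # receives a u-interval of exact length p_k in both partitions, so
  # counts on a fixed u grid agree up to one boundary point per atom
  p <- dpois(0:15, 4)
  us <- seq(0.0005, 0.9995, by = 0.001)
  nat <- findInterval(us, cumsum(p / sum(p))) # natural-order draws
  reord <- vapply(us, function(u) ac_draw_discrete(p, 4, u), 0)
  cnt_n <- tabulate(nat + 1L, 16L)
  cnt_r <- tabulate(reord + 1L, 16L)
  expect_lte(max(abs(cnt_n - cnt_r)), 2L)
})

test_that("discrete stage draws match the stage pmf (chi-square GOF)", {
  set.seed(31)
  dist <- ac_dist(ac_margin("poisson"), mu = c(2, 3),
                  Gamma = matrix(c(.2, .12, .12, .3), 2))
  st <- ac_stage_density(dist, 2, r_prev = 0.9)
  pm <- apxcopula:::.stage_pmf(ac_margin("poisson"), 3,
                               b0 = st$a, b1 = st$b,
                               b2 = st$G[1, 1] / 2)
  draws <- vapply(runif(1e5), function(u)
    ac_draw_discrete(pm$prob, 3, u, pm$support), 0)
  keep <- pm$prob > 1e-6 / length(pm$prob)
  obs <- tabulate(match(draws, pm$support), length(pm$support))
  gof <- suppressWarnings(
    chisq.test(obs[keep], p = pm$prob[keep] / sum(pm$prob[keep])))
  expect_gt(gof$p.value, 0.001)
})

test_that("Gaussian stage inversion matches quadrature and base quantiles", {
  st <- apxcopula:::ac_tilted(list(ac_margin("gaussian", tau2 = 1.2)),
                              mu = 0.5, a = 1.4, b = 0.6,
                              G = matrix(0.5, 1, 1))
  # closed-form CDF against adaptive quadrature
  for (z in c(-2, -0.5, 0, 1, 2.5)) {
    quad <- integrate(function(t) dnorm(t) *
                        (1.4 + 0.6 * t + 0.25 * t^2) / (1.4 + 0.25),
                      -Inf, z, rel.tol = 1e-12)$value
    expect_equal(apxcopula:::.gauss_stage_cdf(z, 1.4, 0.6, 0.25), quad,
                 tolerance = 1e-10)
  }
  # no polynomial tilt: inversion reduces to the base quantile function
  flat <- apxcopula:::ac_tilted(list(ac_margin("gaussian", tau2 = 1.2)),
                                mu = 0.5, a = 1, b = 0,
                                G = matrix(0, 1, 1))
  us <- c(0.025, 0.3, 0.5, 0.9)
  expect_equal(ac_draw_continuous(flat, us),
               qnorm(us, 0.5, sqrt(1.2)), tolerance = 1e-9)
  # KS test of draws against the stage CDF
  set.seed(41)
  draws <- ac_draw_continuous(st, runif(1e5))
  ks <- suppressWarnings(ks.test(draws, function(x)
    apxcopula:::.gauss_stage_cdf((x - 0.5) / sqrt(1.2), 1.4, 0.6,
                                 0.25)))
  expect_gt(ks$p.value, 0.001)
})

test_that("sampled vectors reproduce exact moments and independence", {
  set.seed(21)
  # Gamma = 0: cross-correlation at the Monte Carlo scale
  d0 <- ac_dist(ac_margin("poisson"), mu = c(2, 3),
                Gamma = matrix(0, 2, 2))
  Y0 <- rac(4e4, d0)
  expect_lt(abs(cor(Y0)[1, 2]), 4 / sqrt(4e4))
  # correlated case: mean and covariance within 4 Monte Carlo SEs
  dist <- ac_dist(ac_margin("poisson"), mu = c(2, 3),
                  Gamma = matrix(c(.1, .08, .08, .1), 2))
  n <- 2e5
  Y <- rac(n, dist)
  m <- ac_moments(dist)
  se_mean <- sqrt(diag(m$cov) / n)
  expect_true(all(abs(colMeans(Y) - m$mean) < 4 * se_mean))
  expect_lt(abs(cov(Y)[1, 2] - m$cov[1, 2]),
            4 * sd(scale(Y[, 1], scale = FALSE) *
                     scale(Y[, 2], scale = FALSE)) / sqrt(n))
  # mixed margins, including the continuous stage
  dm <- ac_dist(list(ac_margin("gaussian", tau2 = 0.5),
                     ac_margin("bernoulli")),
                mu = c(1, 0.4), Gamma = matrix(c(.3, .15, .15, .2), 2))
  Ym <- rac(1e5, dm)
  mm <- ac_moments(dm)
  expect_true(all(abs(colMeans(Ym) - mm$mean) <
                    4 * sqrt(diag(mm$cov) / 1e5)))
})

test_that("empirical joint pmf matches the density (chi-square GOF)", {
  set.seed(22)
  dist <- ac_dist(list(ac_margin("poisson"), ac_margin("bernoulli")),
                  mu = c(2, 0.4),
                  Gamma = matrix(c(.2, .1, .1, .15), 2))
  n <- 1e5
  Y <- rac(n, dist)
  grid <- expand.grid(y1 = 0:9, y2 = 0:1)
  p <- dac(as.matrix(grid), dist)
  obs <- vapply(seq_len(nrow(grid)), function(i)
    sum(Y[, 1] == grid$y1[i] & Y[, 2] == grid$y2[i]), 0)
  keep <- p * n > 5
  gof <- suppressWarnings(chisq.test(
    c(obs[keep], n - sum(obs[keep])),
    p = c(p[keep], 1 - sum(p[keep]))))
  expect_gt(gof$p.value, 0.001)
})

test_that("identical seeds give identical streams", {
  dist <- ac_dist(list(ac_margin("gaussian", tau2 = 1),
                       ac_margin("poisson")),
                  mu = c(0, 2), Gamma = 0.2 * diag(2))
  set.seed(99); A <- rac(500, dist)
  set.seed(99); B <- rac(500, dist)
  expect_identical(A, B)
})

test_that("continuous stage sampling outside the Gaussian base errors", {
  st <- apxcopula:::ac_tilted(list(ac_margin("poisson")), mu = 2,
                              a = 1, b = 0, G = matrix(0, 1, 1))
  expect_error(ac_draw_continuous(st, 0.5), "Gaussian")
})
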