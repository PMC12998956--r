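#' Synthetic longitudinal data
#'
#' Generates clustered count/binary/continuous data for recovery
#' studies.  Scenario `"I"` draws responses from the approximate-copula
#' density itself (random-intercept-like variance-component tilt,
#' `Gamma_i = theta * 11'`); scenario `"II"` draws from a random
#' intercept GLMM with a shared Gaussian intercept
#' `b_i ~ N(0, theta)`, providing a misspecified-truth design.
#' Covariates are independent standard normals; the true coefficients
#' (including the intercept) are drawn once from Uniform(-0.2, 0.2).
#'
#' @param scenario `"I"` (approximate-copula truth) or `"II"` (GLMM
#'   truth).
#' @param n number of independent units.
#' @param d observations per unit.
#' @param family base family name.
#' @param theta true variance component (tilt weight for `"I"`,
#'   random-intercept variance for `"II"`).
#' @param p number of non-intercept covariates.
#' @param r negative-binomial dispersion (when `family = "nbinom"`).
#' @param tau2 Gaussian base variance (when `family = "gaussian"`).
#' @param beta optional true coefficient vector of length `p + 1`
#'   (intercept first); drawn uniformly if `NULL`.
#' @param seed optional RNG seed (the generator is a pure function of
#'   it).
#' @return list with `data` (long-format data frame: `id`, `time`,
#'   `y`, `x1..xp`), `units` (an [ac_units()] object ready to fit),
#'   and `truth`.
#' @export
sim_longitudinal <- function(scenario = c("I", "II"), n = 1000, d = 5,
                             family = "poisson", theta = 0.1, p = 3,
                             r = 10, tau2 = 1, beta = NULL,
                             seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  margin <- ac_margin(family, tau2 = tau2, r = r)
  if (is.null(beta)) beta <- stats::runif(p + 1, -0.2, 0.2)
  X <- cbind(rep(1, n * d), matrix(stats::rnorm(n * d * p), n * d, p))
  colnames(X) <- c("(Intercept)", if (p > 0) paste0("x", seq_len(p)))
  eta <- drop(X %*% beta)
  mu <- linkinv_derivs(margin$link, eta)$mu
  Mu <- matrix(mu, n, d, byrow = TRUE)      # rows grouped by unit
  if (scenario == "I") {
    G <- theta * matrix(1, d, d)
    Y <- .sample_tilted_matrix(rep(list(margin), d), Mu, G)
  } else {
    b <- stats::rnorm(n, 0, sqrt(theta))
    eta2 <- matrix(eta, n, d, byrow = TRUE) + b
    mu2 <- linkinv_derivs(margin$link, as.vector(eta2))$mu
    Y <- matrix(switch(family,
      poisson  = stats::rpois(n * d, mu2),
      nbinom   = stats::rnbinom(n * d, size = r, mu = mu2),
      bernoulli = stats::rbinom(n * d, 1, mu2),
      gaussian = stats::rnorm(n * d, mu2, sqrt(tau2))), n, d)
  }
  id <- rep(seq_len(n), each = d)
  dat <- data.frame(id = id, time = rep(seq_len(d), n),
                    y = as.vector(t(Y)), X[, -1L, drop = FALSE])
  units <- ac_units(dat$y, X, id, margin, gamma_vc("intercept"))
  list(data = dat, units = units,
       truth = list(scenario = scenario, beta = beta, theta = theta,
                    family = family, r = r, tau2 = tau2))
}

#' Synthetic multivariate GWAS data
#'
#' Emulates the multivariate simulation designs: `n` subjects with
#' `p` standard-normal covariates (plus intercept), `q` independent
#' SNPs with minor-allele dosages `Binomial(2, maf)`, and `d`
#' correlated responses whose dependence follows the AR1 matrix
#' `Gamma` with unit scale and `rho = 0.5`.  True covariate effects
#' are Uniform(0, 0.5).  `k` causal SNPs receive trait effects
#' `alpha` drawn as Dirichlet(1,...,1) weights scaled to sum to `s`,
#' so each causal SNP influences every trait with correlated random
#' magnitudes.
#'
#' Scenario `"III"` assigns each response a base family drawn from
#' Gaussian (variance 0.5), Bernoulli, and Poisson and samples from
#' the approximate-copula density; `"IV"` makes all responses
#' Bernoulli; `"V"` draws multivariate Gaussian responses
#' `y = B'x + N(0, Gamma)` directly (the collapse-to-base check).
#'
#' @param scenario `"III"`, `"IV"`, or `"V"`.
#' @param n,p,q,d,k design sizes (subjects, covariates, SNPs,
#'   responses, causal SNPs).
#' @param s total causal effect per SNP (`sum(alpha) = s`).
#' @param maf minor-allele frequency of the simulated dosages.
#' @param seed optional RNG seed.
#' @return list with `phenotypes` (`n x d` matrix), `covariates`
#'   (`n x (p+1)` matrix with intercept), `genotypes` (`n x q` dosage
#'   matrix), `families` (length `d`), `margins`, and `truth`
#'   (`B`, `Gamma`, `causal`, `alpha`).
#' @export
sim_multivariate_gwas <- function(scenario = c("III", "IV", "V"),
                                  n = 5000, p = 15, q = 1000, d = 4,
                                  k = 10, s = 0.5, maf = 0.3,
                                  seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  X <- cbind(matrix(stats::rnorm(n * p), n, p), 1)
  colnames(X) <- c(paste0("x", seq_len(p)), "(Intercept)")
  B <- matrix(stats::runif((p + 1) * d, 0, 0.5), p + 1, d)
  G <- matrix(stats::rbinom(n * q, 2, maf), n, q)
  colnames(G) <- paste0("snp", seq_len(q))
  causal <- sort(sample.int(q, k))
  w <- matrix(stats::rexp(k * d), k, d)
  alpha <- s * w / rowSums(w)               # Dirichlet(1,..,1) * s
  Gamma <- gamma_materialize(gamma_ar1(), c(1, 0.5), d)
  eta <- X %*% B
  eta <- eta + G[, causal, drop = FALSE] %*% alpha
  families <- switch(scenario,
    III = sample(c("gaussian", "bernoulli", "poisson"), d,
                 replace = TRUE),
    IV = rep("bernoulli", d),
    V = rep("gaussian", d))
  margins <- lapply(families, function(f) ac_margin(f, tau2 = 0.5))
  if (scenario == "V") {
    Y <- eta + matrix(stats::rnorm(n * d), n, d) %*% chol(Gamma)
  } else {
    Mu <- matrix(0, n, d)
    for (j in seq_len(d))
      Mu[, j] <- linkinv_derivs(margins[[j]]$link, eta[, j])$mu
    Y <- .sample_tilted_matrix(margins, Mu, Gamma)
  }
  colnames(Y) <- paste0("y", seq_len(d))
  list(phenotypes = Y, covariates = X, genotypes = G,
       families = families, margins = margins,
       truth = list(scenario = scenario, B = B, Gamma = Gamma,
                    causal = causal, alpha = alpha, s = s, maf = maf))
}

#' Write a multivariate GWAS simulation to disk
#'
#' Writes the phenotype and covariate tables as CSV (keyed by
#' `fid`/`iid`) and the genotypes as a PLINK bed/bim/fam triplet, the
#' formats consumed by [ac_gwas_files()].
#'
#' @param sim output of [sim_multivariate_gwas()].
#' @param prefix path prefix; creates `<prefix>.pheno.csv`,
#'   `<prefix>.covar.csv`, `<prefix>.bed/.bim/.fam`.
#' @return the prefix, invisibly.
#' @export
write_gwas_sim <- function(sim, prefix) {
  n <- nrow(sim$phenotypes)
  ids <- data.frame(fid = paste0("F", seq_len(n)),
                    iid = paste0("I", seq_len(n)))
  utils::write.csv(cbind(ids, as.data.frame(sim$phenotypes)),
                   paste0(prefix, ".pheno.csv"), row.names = FALSE)
  covar <- as.data.frame(sim$covariates)
  covar <- covar[, colnames(covar) != "(Intercept)", drop = FALSE]
  utils::write.csv(cbind(ids, covar), paste0(prefix, ".covar.csv"),
                   row.names = FALSE)
  write_plink(prefix, sim$genotypes,
              fam = data.frame(fid = ids$fid, iid = ids$iid, pat = 0,
                               mat = 0, sex = 0, pheno = -9))
  invisible(prefix)
}
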