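---
title: "Approximate-copula models: methods and numerical choices"
author: "apxcopula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate-copula models: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apxcopula)
```

## The model

`apxcopula` models a vector $Y = (Y_1, \dots, Y_d)$ of correlated
responses of mixed type by tilting a product of independent base
densities $f_k$ with a quadratic form in standardized residuals:

$$
g(y) \;=\; \Big[1 + \tfrac12\,\mathrm{tr}(\Gamma)\Big]^{-1}
\prod_{k=1}^d f_k(y_k)\,
\Big[1 + \tfrac12\, r^\top \Gamma\, r\Big],
\qquad r_k = \frac{y_k - \mu_k}{\sigma_k},
$$

where $\Gamma$ is positive semidefinite.  Because the base product has
$E[r] = 0$ and $E[r r^\top] = I$, the bracket has expectation
$1 + \mathrm{tr}(\Gamma)/2$ under independence, which is exactly the
normalizing constant: the density needs no determinant, matrix inverse,
or integral.  Off-diagonal entries of $\Gamma$ act approximately as
correlations between components; diagonal entries inflate marginal
variances.  The family is *not* a copula — margins are preserved only
approximately, to first order in $\Gamma$ — but in exchange every
quantity needed for likelihood work is available in closed form:

* **Moments.** The package implements the exact (un-expanded) moment
  expressions; for example
  $E(Y_k) = \mu_k + c^{-1} c_{k3} \gamma_{kk} / (2\sigma_k^2)$ with
  $c = 1 + \mathrm{tr}(\Gamma)/2$ and $c_{k3}$ the third central moment
  of the base.  The familiar small-$\Gamma$ expansions (error of order
  $\|\Gamma\|^2$) are available via `ac_moments(dist, expand = TRUE)`
  for comparison; the tests verify that the gap between the two decays
  at the quadratic rate.
* **Marginals and conditionals.** Integrating out a subset of
  components, or conditioning on it, returns a density of the *same*
  tilted shape, with a modified constant, an added linear term, and the
  restricted $\Gamma$ block.  `ac_marginal()` and `ac_conditional()`
  return these as evaluable objects, and the test suite confirms them
  against brute-force summation of the joint.
* **Sampling.** `rac()` draws component-by-component: the first
  coordinate from its marginal, each later one from its univariate
  conditional given the realized residuals.  Every stage is a base
  density times a quadratic polynomial in $r$, so discrete stages are
  sampled by inversion over a truncated support and Gaussian stages by
  inverting a closed-form CDF built from the partial moments
  $\int_{-\infty}^x y\,\phi(y)\,dy = -\phi(x)$ and
  $\int_{-\infty}^x y^2 \phi(y)\,dy = \Phi(x) - x\phi(x)$.

Supported base families are Gaussian (identity link, noise variance
$\tau^2$), Bernoulli (logit), Poisson (log), and negative binomial (log
link, dispersion $r$, variance $\mu + \mu^2/r$).  Each is paired with
its canonical link only; other pairs are rejected at construction.

## Dependence structures

The per-unit matrix $\Gamma_i$ can be parameterized as

| structure | parameters | form |
|---|---|---|
| variance components | $\theta_j \ge 0$ | $\sum_j \theta_j \Omega_{ij}$ with known PSD $\Omega_{ij}$ |
| AR(1) | $\sigma^2 \ge 0$, $\rho \in (-1,1)$ | entries $\sigma^2 \rho^{|k-l|}$ |
| compound symmetry | $\sigma^2 \ge 0$, $\rho \in [-1/(d_{\max}-1), 1]$ | $\sigma^2[\rho 11^\top + (1-\rho) I]$ |
| unstructured | $\mathrm{vech}(L)$, $\ell_{ii} \ge 0$ | $LL^\top$ |

The admissible $\rho$ ranges are exactly the PSD regions; the only
constraint on the unstructured factor is the nonnegative diagonal.
The loglikelihood touches $\Gamma_i$ only through $\mathrm{tr}(\Gamma_i)$
and $r_i^\top \Gamma_i r_i$, so each structure exposes those two
functionals and their exact parameter derivatives
(`gamma_trace_quad()`, `gamma_grad_trace_quad()`).  For the
variance-component structure we work with the halved quantities
$b_{ij} = r_i^\top \Omega_{ij} r_i / 2$ and
$c_{ij} = \mathrm{tr}(\Omega_{ij})/2$, so that the dependence part of
the loglikelihood is exactly
$\sum_i \log(1 + \theta^\top b_i) - \sum_i \log(1 + \theta^\top c_i)$;
the halves originate in the $\tfrac12$ inside both logarithms.

## Estimation

`acm()` (formula interface) and `acm_fit()` (assembled units) maximize
the loglikelihood

$$
\mathcal{L}(\beta, \theta)
= \sum_i \Big\{ \textstyle\sum_j \log f_{ij}(y_{ij} \mid \beta)
  - \log\big[1 + \tfrac12 \mathrm{tr}\,\Gamma_i(\theta)\big]
  + \log\big[1 + \tfrac12 r_i(\beta)^\top \Gamma_i(\theta)\, r_i(\beta)\big]\Big\}
$$

in three phases:

1. **Initialization.** $\beta$ starts at the independent base-model MLE
   (damped Fisher scoring over the stacked mixed-family design);
   variance components start from the multiplicative MM update
   $\theta_j \leftarrow \theta_j
   \frac{\sum_i b_{ij}/(1+\theta^\top b_i)}
        {\sum_i c_{ij}/(1+\theta^\top c_i)}$,
   which minorizes the concave $\log(1+\theta^\top b_i)$ terms by
   Jensen's inequality and the convex $-\log(1+\theta^\top c_i)$ terms
   by tangents, hence never decreases the loglikelihood and preserves
   nonnegativity.  AR(1)/CS start from the MM scale estimate with
   $\rho = 0$; the unstructured factor starts at the Cholesky factor of
   the sample correlation of the responses (ridged by $10^{-3}$ for
   rank safety).
2. **Block ascent** (default up to 30 cycles, stopping when a cycle
   gains less than `switch_tol = 1e-4`): a Newton step on $\beta$ using
   the negative semidefinite approximate Hessian (expected base
   information plus the score outer-product term) with Armijo step
   halving; MM sweeps (VC) or a short BFGS profile optimization (other
   structures) on the dependence block; one profile Newton step in
   $\log$-scale for each nuisance ($\tau^2$, $r$), with golden-section
   fallback when the curvature is not usable.  Every sub-step is
   monotone, and the iteration trace records the loglikelihood.
3. **Joint polish.** A BFGS pass over all transformed parameters
   ($\log \sigma^2$/$\log \theta_j$, $\mathrm{atanh}$- or logistic-mapped
   $\rho$, $\log$ diagonal of $L$, $\log$ nuisances), followed — if the
   gradient is still above tolerance — by full joint Newton steps whose
   curvature combines the exact observed $\beta$ Hessian with
   finite-difference columns of the analytic score for the dependence
   and nuisance blocks.  These columns capture the $\beta$–$\theta$
   cross-coupling that makes pure block ascent crawl near the optimum.
   Coordinates bounded below by zero (variance components, $\sigma^2$,
   diagonal of $L$) that sit at the boundary with an inward-pointing
   gradient are frozen (an active-set rule) and reported as exactly
   zero with a boundary flag; convergence is declared when the KKT
   residual — the free-scale gradient with those coordinates removed —
   falls below `gtol_scale * (1 + |loglik|/n)`, floored at `1e-4`.

Warm-started refits (the per-SNP alternative models in the GWAS
procedure) skip phases 1–2 and go straight to the joint Newton steps,
which typically converge in three to five iterations.

**Standard errors** are robust sandwich estimates
$A^{-1} B A^{-1}$ over the full $(\beta, \theta, \text{nuisance})$
block: $B$ is the sum of per-unit score outer products
(`ac_unit_scores()`), and $A$ is the negative observed joint Hessian
obtained by central finite differences of the analytic joint score
(one-sided at nonnegativity boundaries).  A singular $A$ falls back to
an eigenvalue pseudo-inverse with a recorded flag.  When a variance
component is estimated on the boundary its standard error is still
reported from the unconstrained sandwich, with the boundary flagged in
the summary.

### Numerical safeguards

Three edge cases deserve mention.

* The logistic link is evaluated through `plogis`, which is stable for
  arbitrarily large linear predictors; nothing is clipped.  At the
  *float* boundary, where $\mu$ rounds to exactly 0 or 1, the generic
  chain-rule ratios become 0/0.  For the Bernoulli margin the package
  therefore uses the cancellation-free canonical forms
  ($\partial \log f / \partial \eta = y - \mu$,
  $\partial r/\partial\eta = -\sigma - r(1-2\mu)/2$, and analogous
  second-order forms), and caps standardized residuals at $10^8$ —
  a magnitude reached only when a binary observation is assigned
  probability below $10^{-16}$.
* With binary components the tilted density has a structural quirk:
  for a badly missed observation the penalty
  $\log f + \log(1 + \tfrac12 r^\top \Gamma r)$ *saturates* instead of
  diverging, so quasi-separated data can push the likelihood onto a
  slowly rising ridge toward infinite coefficients, much like
  separation in logistic regression but with a bounded objective.
  The optimizer handles the region gracefully (finite objective and
  gradients, Armijo-guarded steps) and reports non-convergence
  honestly when the ridge does not level off within the iteration
  budget.  The practical remedy is the usual one: adequate sample size
  relative to the number of predictors per binary trait.
* Dependence parameters live on transformed scales during quasi-Newton
  so that every iterate is feasible; the Newton polish instead works on
  the natural scale with projection plus the active-set rule, which is
  what allows exact zeros.

## The multivariate GWAS procedure

For $d$ traits and a SNP dosage vector $g$, the SNP effect
$\alpha \in \mathbb{R}^d$ enters every trait's linear predictor as
$\eta_{ij} \mathrel{+}= g_i \alpha_j$, and the null hypothesis is
$\alpha = 0$.  The procedure is:

1. Fit the null multivariate model once.
2. **Screen** every SNP by $\|\nabla_\alpha \mathcal{L}\|_1$ evaluated
   at the null MLE.  Because the score with respect to $\alpha_j$ is
   $\sum_i g_i u_{ij}$, where $u_{ij}$ is the per-observation
   linear-predictor score at the null, screening an entire genotype
   block is a single matrix product ($U^\top G$) — no refitting.
3. Select SNPs (default: top 0.1% by screening statistic; a quantile
   rule and test-everything are also available) and run a warm-started
   **likelihood-ratio test** on each: the alternative frees all
   parameters, and $2(\mathcal{L}_a - \mathcal{L}_0)$, clipped below at
   zero, is referred to $\chi^2_d$.  Results are reported with raw and
   Bonferroni-adjusted p-values and the conventional $5\times10^{-8}$
   genome-wide flag.

Screening only *selects*: the tested SNPs' statistics are identical
with and without screening, and a block-partitioned run equals a
single-block run record for record.  Missing dosages are imputed to the
per-SNP mean (standard GWAS practice; the model itself has no
missing-data mechanism), and monomorphic SNPs are flagged with a zero
statistic.  PLINK bed/bim/fam triplets are read and written natively
(`read_plink()`, `write_plink()`); no relatedness or
population-structure correction is attempted.

## Synthetic-data generators

Two generators reproduce the designs used throughout the validation
suite; both are pure functions of their seed.

* `sim_longitudinal()` — clustered data with standard-normal
  covariates and true coefficients (intercept included) drawn once from
  Uniform(−0.2, 0.2).  Scenario `"I"` samples responses from the
  approximate-copula density itself with the random-intercept-style
  tilt $\Gamma_i = \theta 11^\top$ ($\theta = 0.1$ by default);
  scenario `"II"` samples from a random-intercept GLMM with
  $b_i \sim N(0, \theta)$, $\theta = 0.05$ by default, providing a
  misspecified-truth design.  The negative-binomial dispersion defaults
  to $r = 10$.  Whether the intercept is part of the uniform
  coefficient law is a free choice; we include it for symmetry.
* `sim_multivariate_gwas()` — $n$ subjects, $p$ standard-normal
  covariates plus intercept, $q$ SNPs with Binomial(2, 0.3) dosages,
  $d = 4$ responses, dependence fixed at the unit-scale AR(1) matrix
  with $\rho = 0.5$.  Covariate effects are Uniform(0, 0.5).  Scenario
  `"III"` mixes Gaussian ($\tau^2 = 0.5$), Bernoulli, and Poisson
  margins; `"IV"` is all-Bernoulli; `"V"` is multivariate Gaussian
  $y = B^\top x + N(0, \Gamma)$ sampled directly, for
  collapse-to-base checks.  Each of the $k$ causal SNPs receives
  nonnegative per-trait effects drawn as Dirichlet(1, …, 1) weights
  scaled to sum to the budget $s$ — "correlated and random" magnitudes
  under the stated sum constraint; the drawn values are returned in the
  `truth` element so harnesses are self-describing.

What these generators deliberately do **not** emulate: linkage
disequilibrium between SNPs (dosages are independent), population
structure or relatedness, missing genotypes (tests inject them
separately), covariate measurement error, and informative cluster
sizes.  Passing recovery tests on these designs therefore demonstrates
correctness of the estimator under the model's own assumptions, not
robustness to those real-data complications.

## Validation harness sizes

The statistical checks run at sizes chosen to give stable Monte Carlo
verdicts while keeping the full suite fast on a single core:

* recovery: Poisson scenario-I fits at $n \in \{100, 1000, 10000\}$,
  cluster sizes 2 and 5, 20 replicates (10 in the standalone
  acceptance script) — mean squared errors of $\hat\beta$ and
  $\hat\theta$ must fall monotonically in $n$;
* sampler goodness of fit at $10^5$ draws;
* null calibration of the screened LRT on 2000 null SNPs from the
  mixed-margin multivariate design at $n = 1000$ subjects and 5
  covariates — the reduced covariate count keeps the per-trait logistic
  sub-models far from quasi-separation at this sample size (see the
  ridge discussion above), which is a property of the design scale,
  not of the test being checked;
* screening-versus-exact-ordering rank correlation on 1000 SNPs (700 in
  the in-suite assertion) with 10 causal SNPs at total effect
  $s = 0.5$.

### How faithful is the screening order?

For null SNPs the screening statistic and the LRT are two functionals
of the same trait-score vector $S = \nabla_\alpha \mathcal{L}$:
$\|S\|_1$ versus (asymptotically) the Mahalanobis form
$S^\top V^{-1} S$ with $V = \mathrm{Var}(S)$.  Their rank agreement is
therefore a closed property of $V$, computable by simulating
$S \sim N(0, V)$.  When the traits carry comparable score scales the
Spearman correlation between the two orderings is about 0.94–0.96;
when the drawn trait mix is strongly heterogeneous (binary traits
carry far less information per observation than Gaussian or Poisson
ones, e.g. score standard deviations 8/33/26/7 across four traits) it
drops to about 0.8, because the $\ell_1$ norm under-weights the
low-information components that the LRT standardizes.  The package
reports the plain $\ell_1$ statistic; users screening strongly
heterogeneous trait panels should either deepen the selection rule
(larger `k`) or screen on a per-trait standardized score of their own
construction.

## Known limitations

* Margins are only approximately preserved; diagonal tilt inflates
  variances, which is a feature when data are overdispersed relative
  to the base and a bias otherwise.
* When unit sizes are large or correlations strong, the normalizing
  constant grows and shrinks $\hat\Gamma$ toward zero; variance
  components are then unreliable even though mean-effect estimates
  remain stable.  Treat $\Gamma$ as a nuisance in that regime.
* Conditional moments are evaluated from the conditional density, not
  from closed-form expressions; only the second-order agreement between
  conditional and marginal moments is asserted.
* Continuous-stage sampling is implemented for the Gaussian base only;
  other continuous bases are rejected with a clear error.
* The low-rank variant of the unstructured factor is not implemented.
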