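Package: apxcopula
Title: Approximate-Copula Models for Correlated Non-Gaussian Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Likelihood-based modelling of clustered and multivariate
    responses with Gaussian, Bernoulli, Poisson, or negative-binomial
    margins through an approximate-copula density: an independent base
    product tilted by a quadratic form in standardized residuals and
    normalized in closed form.  The density admits exact moments,
    marginal and conditional distributions, sequential random sampling,
    and analytic scores and Hessians, so maximum likelihood estimation
    proceeds without numerical integration.  Dependence within a
    sampling unit is parameterized by variance-component, AR(1),
    compound-symmetry, or unstructured Cholesky forms.  Includes robust
    sandwich standard errors, synthetic-data generators for simulation
    studies, and a fast multivariate genome-wide association procedure
    that screens variants by the l1 norm of the score and confirms the
    top hits with likelihood-ratio tests against PLINK binary genotype
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
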