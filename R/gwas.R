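#' Score screening of SNPs under a fitted null model
#'
#' For each SNP `g`, the score of the loglikelihood with respect to
#' the per-trait SNP effects `alpha` (entering every trait's linear
#' predictor as `eta_ij + g_i alpha_j`), evaluated at the null MLE
#' with `alpha = 0`.  The score reduces to `U'g` where `U` is the
#' `n x d` matrix of per-observation linear-predictor scores at the
#' null, so screening an entire genotype block is one matrix product
#' and needs no refitting.  The l1 norm `||grad_alpha L||_1` is the
#' screening statistic.
#'
#' @param fit a converged `"acm"` null model over balanced units.
#' @param G `n x q` dosage matrix (entries 0/1/2 or `NA`; missing
#'   dosages are imputed to the SNP mean).
#' @return list with `stat` (length-q screening statistics),
#'   `score` (`d x q` matrix of alpha-scores), and logical
#'   `monomorphic` (those SNPs get statistic 0).
#' @export
ac_score_screen <- function(fit, G) {
  units <- fit$units
  d <- unique(units$d_i)
  if (length(d) != 1L)
    stop("score screening requires balanced units")
  n <- units$n
  stopifnot(nrow(G) == n)
  ev <- ac_eval(units, fit$beta, fit$theta, fit$nuis)
  U <- matrix(ev$w_beta[order(units$unit, units$pos)], n, d,
              byrow = TRUE)                  # d L / d eta_ij
  G <- impute_dosage(G)
  mono <- apply(G, 2L, function(g) stats::var(g) == 0)
  S <- crossprod(U, G)                       # d x q alpha-scores
  stat <- colSums(abs(S))
  stat[mono] <- 0
  list(stat = stat, score = S, monomorphic = mono)
}

impute_dosage <- function(G) {
  miss <- is.na(G)
  if (any(miss)) {
    mcol <- colMeans(G, na.rm = TRUE)
    G[miss] <- mcol[col(G)[miss]]
  }
  G
}

# units augmented with one SNP-effect column per trait position
augment_units_snp <- function(units, g) {
  d <- unique(units$d_i)
  stopifnot(length(d) == 1L, length(g) == units$n)
  N <- length(units$y)
  Gblock <- matrix(0, N, d)
  colnames(Gblock) <- paste0("alpha", seq_len(d))
  for (j in seq_len(d))
    Gblock[units$pos == j, j] <- g[units$unit[units$pos == j]]
  units2 <- units
  units2$X <- cbind(units$X, Gblock)
  units2$P <- ncol(units2$X)
  units2
}

#' Likelihood-ratio test of a SNP's multivariate effect
#'
#' Fits the alternative model with the `d`-vector of trait effects
#' `alpha` free (all other parameters also free, warm-started at the
#' null estimates) and refers `2(La - L0)`, clipped below at zero, to
#' a chi-square distribution with `d` degrees of freedom.
#'
#' @param fit the fitted `"acm"` null model.
#' @param g dosage vector over the `n` units (missing imputed to the
#'   mean).
#' @param control an [acm_control()] for the alternative fit.
#' @return list with `lrt`, `df`, `p`, `alpha` (estimated trait
#'   effects), and `converged`.
#' @export
ac_lrt <- function(fit, g,
                   control = acm_control(block_iters = 0L, qn_maxit = 0L)) {
  g <- as.numeric(g)
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  units2 <- augment_units_snp(fit$units, g)
  d <- unique(fit$units$d_i)
  # one Fisher-scoring step on alpha from zero shortens the refit
  ev <- ac_eval(fit$units, fit$beta, fit$theta, fit$nuis)
  n <- fit$units$n
  U <- matrix(ev$w_beta, n, d, byrow = TRUE)
  W <- matrix(ev$wJ, n, d, byrow = TRUE)
  alpha0 <- drop(crossprod(U, g)) / pmax(drop(crossprod(W, g^2)),
                                         1e-10)
  start <- list(beta = c(fit$beta, alpha0), theta = fit$theta,
                nuis = fit$nuis)
  alt <- acm_fit(units2, control, start = start, sandwich = FALSE)
  stat <- max(2 * (alt$loglik - fit$loglik), 0)
  list(lrt = stat, df = d,
       p = if (alt$converged) stats::pchisq(stat, d, lower.tail = FALSE)
           else NA_real_,
       alpha = unname(alt$beta[fit$units$P + seq_len(d)]),
       converged = alt$converged)
}

#' Screened likelihood-ratio multivariate GWAS
#'
#' The fast genome-wide procedure: (1) fit (or accept) the null
#' multivariate model once; (2) stream the genotype matrix in blocks
#' and compute every SNP's screening statistic `||grad_alpha L||_1`;
#' (3) select SNPs by the configured rule; (4) run a warm-started
#' likelihood-ratio test on each selected SNP; (5) return the full
#' per-SNP table.  Screening only selects: the LRT statistic of a SNP
#' does not depend on whether other SNPs were screened out.
#'
#' @param fit the fitted `"acm"` null model (no SNP terms).
#' @param G `n x q` dosage matrix.
#' @param bim optional variant map (`chr`, `id`, `pos`, `a1`, `a2`
#'   columns) aligned with the columns of `G`.
#' @param select selection rule: `"topk"` (default, the `k` largest
#'   screening statistics), `"quantile"` (all SNPs above the
#'   `screen_quantile` quantile), or `"all"`.
#' @param k number of SNPs advanced to testing under `"topk"`
#'   (default 0.1 percent of `q`, at least 1).
#' @param screen_quantile quantile for `select = "quantile"`.
#' @param block_size SNPs per screening block (blocks are
#'   independent; a partitioned run equals a single-block run).
#' @param control an [acm_control()] for the alternative fits.
#' @return a data frame with one row per SNP: `snp`, `chr`, `pos`,
#'   `a1`, `a2`, `maf`, `screen_stat`, `lrt`, `df`, `p`,
#'   `p_bonferroni`, `sig_5e8`, `alpha_1..alpha_d`, `tested`,
#'   `monomorphic`, `lrt_converged`.
#' @export
ac_gwas <- function(fit, G, bim = NULL,
                    select = c("topk", "quantile", "all"),
                    k = NULL, screen_quantile = 0.999,
                    block_size = 1000L,
                    control = acm_control(block_iters = 0L, qn_maxit = 0L)) {
  select <- match.arg(select)
  q <- ncol(G)
  d <- unique(fit$units$d_i)
  if (is.null(k)) k <- max(1L, ceiling(0.001 * q))
  blocks <- split(seq_len(q), (seq_len(q) - 1L) %/% block_size)
  stat <- numeric(q); mono <- logical(q)
  for (b in blocks) {
    sc <- ac_score_screen(fit, G[, b, drop = FALSE])
    stat[b] <- sc$stat; mono[b] <- sc$monomorphic
  }
  tested <- switch(select,
    topk = seq_len(q) %in% utils::head(order(stat, decreasing = TRUE),
                                       k),
    quantile = stat >= stats::quantile(stat, screen_quantile),
    all = rep(TRUE, q))
  tested <- tested & !mono
  Gi <- impute_dosage(G)
  maf <- colMeans(Gi) / 2
  maf <- pmin(maf, 1 - maf)
  out <- data.frame(
    snp = colnames(G) %||% paste0("snp", seq_len(q)),
    chr = if (!is.null(bim)) bim$chr else NA,
    pos = if (!is.null(bim)) bim$pos else NA,
    a1 = if (!is.null(bim)) bim$a1 else NA,
    a2 = if (!is.null(bim)) bim$a2 else NA,
    maf = maf, screen_stat = stat, lrt = NA_real_, df = d,
    p = NA_real_, p_bonferroni = NA_real_, sig_5e8 = NA,
    tested = tested, monomorphic = mono, lrt_converged = NA)
  al <- matrix(NA_real_, q, d,
               dimnames = list(NULL, paste0("alpha_", seq_len(d))))
  for (j in which(tested)) {
    lr <- ac_lrt(fit, Gi[, j], control)
    out$lrt[j] <- lr$lrt; out$p[j] <- lr$p
    out$lrt_converged[j] <- lr$converged
    al[j, ] <- lr$alpha
  }
  out$p_bonferroni <- pmin(out$p * q, 1)
  out$sig_5e8 <- !is.na(out$p) & out$p < 5e-8
  cbind(out, al)
}

#' File-based GWAS driver
#'
#' Reads a phenotype CSV and covariate CSV (both keyed by `fid`,`iid`)
#' and a PLINK bed/bim/fam triplet, aligns samples by id (a mismatch
#' is a hard error listing the orphans; phenotype rows with missing
#' values are dropped with a message), fits the multivariate null
#' model, and runs [ac_gwas()].
#'
#' @param pheno_csv CSV with columns `fid`, `iid`, then one column per
#'   trait.
#' @param covar_csv CSV with columns `fid`, `iid`, then covariates
#'   (an intercept is added automatically).
#' @param bed_prefix PLINK file prefix.
#' @param families base family per trait column.
#' @param ... passed to [ac_gwas()].
#' @return list with `null_fit` and `results` (the [ac_gwas()] table
#'   with `chr`/`pos`/alleles from the bim file).
#' @export
ac_gwas_files <- function(pheno_csv, covar_csv, bed_prefix, families,
                          ...) {
  ph <- utils::read.csv(pheno_csv, check.names = FALSE)
  cv <- utils::read.csv(covar_csv, check.names = FALSE)
  pl <- read_plink(bed_prefix)
  key <- function(df) paste(df$fid, df$iid, sep = "\r")
  orphans <- c(setdiff(key(pl$fam), key(ph)), setdiff(key(ph),
                                                      key(pl$fam)))
  if (length(orphans))
    stop("sample ids do not match between fam and phenotype files: ",
         paste(gsub("\r", "/", utils::head(orphans, 5L)),
               collapse = ", "))
  ph <- ph[match(key(pl$fam), key(ph)), , drop = FALSE]
  cv <- cv[match(key(pl$fam), key(cv)), , drop = FALSE]
  keep <- stats::complete.cases(ph) & stats::complete.cases(cv)
  if (any(!keep))
    message("dropping ", sum(!keep), " samples with missing rows")
  Y <- as.matrix(ph[keep, setdiff(names(ph), c("fid", "iid")),
                    drop = FALSE])
  X <- as.matrix(cv[keep, setdiff(names(cv), c("fid", "iid")),
                    drop = FALSE])
  dat <- data.frame(X, check.names = TRUE)
  fml <- stats::as.formula(paste("Y ~", paste(names(dat),
                                              collapse = " + ")))
  dat$Y <- Y
  fit <- acm(fml, dat, family = families, structure = "unstructured")
  res <- ac_gwas(fit, pl$genotypes[keep, , drop = FALSE],
                 bim = pl$bim, ...)
  list(null_fit = fit, results = res)
}

#' Write GWAS results as TSV
#'
#' @param results table from [ac_gwas()].
#' @param path output file.
#' @export
write_gwas_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
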