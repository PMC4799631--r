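# Whole-genome regression: prior derivation, BayesB / BayesC0 wrappers
# around the compiled Gibbs sampler, and GEBV computation.

#' Derive whole-genome regression priors from pedigree variance components
#'
#' The variance of the effect of a randomly sampled SNP is
#' `sigma_tilde_j2 = sigma_s2 / ((1 - pi) * sum_j 2 p_j (1 - p_j))`, where
#' `sigma_s2` is the additive genetic variance attributed to the SNPs
#' (taken from the pedigree REML fit) and `p_j` are allele frequencies
#' from the non-missing genotype calls. The per-SNP variance prior is a
#' scaled inverse chi-square with `nu_j` degrees of freedom and scale
#' `S2_j = sigma_tilde_j2 (nu_j - 2) / nu_j`. The residual prior is a
#' scaled inverse chi-square with `nu_e` degrees of freedom and its scale
#' matched so the prior mean equals the REML residual variance.
#'
#' @param vc Variance components (list with `sigma2_a`, `sigma2_e`), e.g.
#'   from [estimate_variance_components()].
#' @param genotypes A `gw_genotypes` object (supplies allele frequencies).
#' @param pi Prior fraction of SNPs with zero effect (default 0.95).
#' @param nu_j Degrees of freedom of the SNP-variance prior (default 4.2).
#' @param nu_e Degrees of freedom of the residual-variance prior.
#' @return List of class `gw_priors` with `pi`, `nu_j`, `S2_j`,
#'   `sigma_tilde_j2`, `sigma_s2`, `nu_e`, `S2_e` and `sum2pq`.
#' @export
derive_priors <- function(vc, genotypes, pi = 0.95, nu_j = 4.2, nu_e = 10) {
  stopifnot(pi >= 0, pi < 1)
  p <- if (inherits(genotypes, "gw_genotypes")) genotypes$p
       else as.numeric(genotypes)
  sum2pq <- sum(2 * p * (1 - p), na.rm = TRUE)
  if (sum2pq <= 0)
    stop_genwin("derive_priors: all SNPs monomorphic (sum 2pq = 0)")
  sigma_s2 <- vc$sigma2_a
  sigma_tilde_j2 <- sigma_s2 / ((1 - pi) * sum2pq)
  S2_j <- sigma_tilde_j2 * (nu_j - 2) / nu_j
  S2_e <- vc$sigma2_e * (nu_e - 2) / nu_e
  structure(list(pi = pi, nu_j = nu_j, S2_j = S2_j,
                 sigma_tilde_j2 = sigma_tilde_j2, sigma_s2 = sigma_s2,
                 nu_e = nu_e, S2_e = S2_e, sum2pq = sum2pq),
            class = "gw_priors")
}

# Shared front end of the two samplers: align records with genotypes,
# mean-impute missing calls, and order SNP columns by id so that the draw
# stream is keyed by SNP identity (posterior invariant to column
# permutation of the input).
prepare_wgr <- function(genotypes, phenotypes) {
  stopifnot(inherits(genotypes, "gw_genotypes"))
  phenotypes <- phenotypes[!is.na(phenotypes$value), , drop = FALSE]
  ids <- intersect(as.character(phenotypes$id), rownames(genotypes$geno))
  if (length(ids) < 2L)
    stop_genwin("fewer than 2 animals with both genotype and phenotype")
  phenotypes <- phenotypes[match(ids, as.character(phenotypes$id)), ,
                           drop = FALSE]
  ord <- order(genotypes$map$snp_id)
  Z <- impute_genotypes(genotypes)[ids, ord, drop = FALSE]
  cls <- factor(phenotypes$hatch_class)
  list(Z = Z, y = phenotypes$value, ids = ids,
       class_idx = as.integer(cls) - 1L, classes = levels(cls),
       snp_ids = genotypes$map$snp_id[ord],
       p = genotypes$p[ord])
}

wgr_result <- function(res, prep, method, priors, chain_length, burn_in) {
  structure(list(u_hat = setNames(as.numeric(res$u_hat), prep$snp_ids),
                 incl_prob = setNames(as.numeric(res$incl_prob),
                                      prep$snp_ids),
                 beta = setNames(as.numeric(res$beta_hat), prep$classes),
                 chains = list(var_g = as.numeric(res$varg_chain),
                               var_e = as.numeric(res$vare_chain),
                               h2 = as.numeric(res$h2_chain),
                               sigma2_u = as.numeric(res$sigma2_u_chain)),
                 h2_q = mean(res$h2_chain[-seq_len(burn_in)]),
                 h2_q_sd = sd(res$h2_chain[-seq_len(burn_in)]),
                 p = prep$p, train_ids = prep$ids,
                 method = method, priors = priors,
                 chain_length = chain_length, burn_in = burn_in),
            class = "gw_posterior")
}

#' @export
print.gw_posterior <- function(x, ...) {
  cat(sprintf("<gw_posterior> %s, %d SNPs, chain %d (burn-in %d)\n",
              x$method, length(x$u_hat), x$chain_length, x$burn_in))
  cat(sprintf("  marker h2 = %.3f (sd %.3f); mean inclusion = %.3f\n",
              x$h2_q, x$h2_q_sd, mean(x$incl_prob)))
  invisible(x)
}

#' BayesB spike-and-slab whole-genome regression
#'
#' Single-site Gibbs sampler for the model `y_im = beta_m + sum_j z_ij u_j
#' + e_i` in which a fraction `pi` of SNPs has zero effect and each
#' included effect is normal with a SNP-specific variance under a scaled
#' inverse chi-square prior (marginally scaled-t). The inclusion indicator
#' is drawn with the effect integrated out given the current SNP variance;
#' excluded variances are refreshed from the prior.
#'
#' @param genotypes A `gw_genotypes` object (training animals; missing
#'   calls are mean-imputed).
#' @param phenotypes Data frame `id`, `value`, `hatch_class` for one trait.
#' @param priors A [derive_priors()] object.
#' @param chain_length,burn_in MCMC chain length and discarded burn-in.
#' @param seed Integer seed for the chain.
#' @param fix_variances If `TRUE`, hold every SNP variance at `sigma2_u`
#'   and the residual variance at `sigma2_e` (degenerate priors; mainly
#'   for equivalence checks against closed forms).
#' @param sigma2_u,sigma2_e Values used when `fix_variances = TRUE`.
#' @return A `gw_posterior` object: posterior-mean SNP effects `u_hat`,
#'   per-SNP inclusion probabilities, fixed-class posterior means, full
#'   chains for the genetic variance of model-implied genetic values, the
#'   residual variance and the marker heritability, and the posterior
#'   summary `h2_q`.
#' @export
run_bayesb <- function(genotypes, phenotypes, priors,
                       chain_length = 55000, burn_in = 5000, seed = 1L,
                       fix_variances = FALSE, sigma2_u = NULL,
                       sigma2_e = NULL) {
  stopifnot(inherits(priors, "gw_priors"))
  if (chain_length <= burn_in)
    stop_genwin("chain_length must exceed burn_in")
  prep <- prepare_wgr(genotypes, phenotypes)
  su <- sigma2_u %||% (priors$S2_j * priors$nu_j / (priors$nu_j - 2))
  se <- sigma2_e %||% (priors$S2_e * priors$nu_e / (priors$nu_e - 2))
  set.seed(seed)
  res <- .wgr_mcmc_cpp(prep$Z, prep$y, prep$class_idx,
                       length(prep$classes),
                       priors$pi, priors$nu_j, priors$S2_j,
                       priors$nu_e, priors$S2_e,
                       as.integer(chain_length), as.integer(burn_in),
                       FALSE, fix_variances, su, fix_variances, se)
  wgr_result(res, prep, "bayesb", priors, chain_length, burn_in)
}

#' BayesC0 whole-genome regression (common SNP-effect variance)
#'
#' The same Gibbs sweep as [run_bayesb()] but with every SNP kept in the
#' model (`pi = 0`) and a single common effect variance updated from the
#' pooled scaled inverse chi-square full conditional; used for marker-based
#' heritability. With both variances fixed (`fix_variances = TRUE`) the
#' posterior mean of the SNP effects converges to the ridge-regression
#' solution, which makes the sampler directly checkable against a closed
#' form.
#'
#' @inheritParams run_bayesb
#' @param fix_variances If `TRUE`, hold the common SNP variance and the
#'   residual variance at `sigma2_u` / `sigma2_e` (degenerate priors).
#' @param sigma2_u,sigma2_e Values used when `fix_variances = TRUE`
#'   (default: the prior point values implied by `priors`).
#' @param h2_definition `"sample"` (default): the marker-heritability
#'   numerator is the sample variance of model-implied genetic values of
#'   the training animals at each iteration; `"genic"`: the numerator is
#'   `sum_j 2 p_j (1 - p_j)` times the common SNP variance.
#' @return A `gw_posterior` object (all inclusion probabilities are 1).
#' @export
run_bayesc0 <- function(genotypes, phenotypes, priors,
                        chain_length = 55000, burn_in = 5000, seed = 1L,
                        fix_variances = FALSE,
                        sigma2_u = NULL, sigma2_e = NULL,
                        h2_definition = c("sample", "genic")) {
  stopifnot(inherits(priors, "gw_priors"))
  h2_definition <- match.arg(h2_definition)
  if (chain_length <= burn_in)
    stop_genwin("chain_length must exceed burn_in")
  prep <- prepare_wgr(genotypes, phenotypes)
  # with pi = 0 the randomly-sampled-SNP variance formula reduces to
  # sigma_s2 / sum2pq; honour priors derived at any pi by recomputing
  s_tilde <- priors$sigma_s2 / priors$sum2pq
  S2_j <- s_tilde * (priors$nu_j - 2) / priors$nu_j
  su <- sigma2_u %||% (S2_j * priors$nu_j / (priors$nu_j - 2))
  se <- sigma2_e %||% (priors$S2_e * priors$nu_e / (priors$nu_e - 2))
  set.seed(seed)
  res <- .wgr_mcmc_cpp(prep$Z, prep$y, prep$class_idx,
                       length(prep$classes),
                       0, priors$nu_j, S2_j,
                       priors$nu_e, priors$S2_e,
                       as.integer(chain_length), as.integer(burn_in),
                       TRUE, fix_variances, su, fix_variances, se)
  out <- wgr_result(res, prep, "bayesc0", priors, chain_length, burn_in)
  if (h2_definition == "genic") {
    sum2pq <- sum(2 * prep$p * (1 - prep$p))
    vg <- sum2pq * out$chains$sigma2_u
    h2g <- vg / (vg + out$chains$var_e)
    out$chains$h2 <- h2g
    out$h2_q <- mean(h2g[-seq_len(burn_in)])
    out$h2_q_sd <- sd(h2g[-seq_len(burn_in)])
  }
  out
}

#' Genomic estimated breeding values from posterior-mean SNP effects
#'
#' `GEBV_i = sum_j z_ij u_hat_j`, with the same 0/1/2 dosage coding (and
#' the same mean imputation of missing calls) as used in training.
#'
#' @param genotypes A `gw_genotypes` object for the animals to predict.
#' @param u_hat Named vector of posterior-mean SNP effects, or a
#'   `gw_posterior` object.
#' @param p Optional training allele frequencies for imputation (defaults
#'   to the posterior's, then to the target set's own frequencies).
#' @return Data frame `id`, `gebv`.
#' @export
compute_gebv <- function(genotypes, u_hat, p = NULL) {
  stopifnot(inherits(genotypes, "gw_genotypes"))
  if (inherits(u_hat, "gw_posterior")) {
    p <- p %||% u_hat$p
    u_hat <- u_hat$u_hat
  }
  if (is.null(names(u_hat)))
    stop_genwin("u_hat must be named by SNP id")
  missing_snps <- setdiff(names(u_hat), genotypes$map$snp_id)
  extra_snps <- setdiff(genotypes$map$snp_id, names(u_hat))
  if (length(missing_snps) || length(extra_snps))
    stop_genwin("SNP-id mismatch between genotypes and u_hat; offenders: ",
                paste(head(c(missing_snps, extra_snps), 10L),
                      collapse = ", "))
  Z <- impute_genotypes(genotypes, p = p)[, names(u_hat), drop = FALSE]
  data.frame(id = rownames(Z), gebv = as.numeric(Z %*% u_hat),
             stringsAsFactors = FALSE)
}
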