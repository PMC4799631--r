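# Whole-genome regression: priors, BayesB, BayesC0, and GEBV arithmetic.

make_geno <- function(n, p, maf = NULL, seed = 1) {
  set.seed(seed)
  maf <- maf %||% runif(p, 0.1, 0.5)
  g <- sapply(maf, function(q) rbinom(n, 2, q))
  gw_genotypes(g, ids = paste0("a", seq_len(n)))
}

test_that("prior scales follow the printed formulas", {
  vc <- list(sigma2_a = 1, sigma2_e = 0.6)
  geno <- gw_genotypes(matrix(1L, 4, 100), ids = 1:4)
  geno$p <- rep(0.5, 100) # sum 2pq = 50
  pr <- derive_priors(vc, geno, pi = 0.95, nu_j = 4.2)
  expect_equal(pr$sigma_tilde_j2, 1 / (0.05 * 50))        # 0.4
  expect_equal(pr$S2_j, 0.4 * (4.2 - 2) / 4.2)            # ~0.2095
  # pi = 0: the (1 - pi) factor drops out
  pr0 <- derive_priors(vc, geno, pi = 0)
  expect_equal(pr0$sigma_tilde_j2, 1 / 50)
  # default pi matches the spike fraction used throughout
  expect_equal(formals(derive_priors)$pi, 0.95)
  expect_error(derive_priors(vc, gw_genotypes(matrix(0L, 4, 3), ids = 1:4)),
               "monomorphic")
})

test_that("pure-noise phenotypes leave inclusion near the prior", {
  incl <- sapply(1:5, function(s) {
    geno <- make_geno(300, 120, seed = 40 + s)
    set.seed(90 + s)
    phe <- data.frame(id = paste0("a", 1:300), value = rnorm(300),
                      hatch_class = "h1")
    pr <- derive_priors(list(sigma2_a = 0.3, sigma2_e = 0.7), geno)
    post <- run_bayesb(geno, phe, pr, chain_length = 2500, burn_in = 500,
                       seed = s)
    mean(post$incl_prob)
  })
  expect_equal(mean(incl), 0.05, tolerance = 0.5) # 1 - pi, within MC error
  expect_lt(mean(incl), 0.12)
})

test_that("a large tagged QTL is detected and GEBV track true merit", {
  ok_incl <- logical(5); cors <- numeric(5)
  for (s in 1:5) {
    set.seed(2000 + s)
    n <- 600; p <- 80
    qtl <- rbinom(n, 2, 0.4)
    g <- sapply(runif(p - 1, 0.1, 0.5), function(q) rbinom(n, 2, q))
    # panel SNP 1 in high LD with the causal locus
    tag <- ifelse(runif(n) < 0.95, qtl, rbinom(n, 2, 0.4))
    geno <- gw_genotypes(cbind(tag, g),
                         ids = paste0("a", 1:n),
                         map = data.frame(snp_id = sprintf("s%03d", 1:p),
                                          chrom = 1, pos = (1:p) / 100))
    bv <- qtl * 0.8
    y <- bv + rnorm(n, 0, sqrt(0.6))
    phe <- data.frame(id = paste0("a", 1:n), value = y, hatch_class = "h1")
    pr <- derive_priors(list(sigma2_a = var(bv), sigma2_e = 0.6), geno)
    post <- run_bayesb(geno, phe, pr, chain_length = 3000, burn_in = 600,
                       seed = s)
    ok_incl[s] <- post$incl_prob["s001"] > 0.8
    gebv <- compute_gebv(geno, post)
    cors[s] <- cor(gebv$gebv[match(paste0("a", 1:n), gebv$id)], bv)
  }
  expect_gte(sum(ok_incl), 4)
  expect_true(all(cors > 0.6))
})

test_that("BayesC0 with fixed variances matches the ridge closed form", {
  set.seed(77)
  n <- 250; p <- 150
  geno <- make_geno(n, p, seed = 78)
  u_true <- rnorm(p, 0, 0.05)
  y <- as.numeric(impute_genotypes(geno) %*% u_true) + rnorm(n, 0, 0.5)
  phe <- data.frame(id = paste0("a", 1:n), value = y, hatch_class = "h1")
  pr <- derive_priors(list(sigma2_a = 0.3, sigma2_e = 0.25), geno, pi = 0)
  s2u <- 0.002; s2e <- 0.25
  post <- run_bayesc0(geno, phe, pr, chain_length = 12000, burn_in = 2000,
                      seed = 3, fix_variances = TRUE,
                      sigma2_u = s2u, sigma2_e = s2e)
  Z <- impute_genotypes(geno)[, names(post$u_hat)]
  oracle <- ridge_oracle(Z, y, rep("h1", n), s2u, s2e)
  expect_gt(cor(post$u_hat, oracle$u), 0.99)
})

test_that("BayesC0 recovers heritability and collapses under permutation", {
  set.seed(91)
  n <- 700; p <- 300
  geno <- make_geno(n, p, seed = 92)
  Z <- impute_genotypes(geno)
  u_true <- rnorm(p, 0, 1)
  g <- as.numeric(Z %*% u_true)
  g <- (g - mean(g)) / sd(g) * sqrt(0.5) # genetic variance 0.5
  y <- g + rnorm(n, 0, sqrt(0.5))
  phe <- data.frame(id = paste0("a", 1:n), value = y, hatch_class = "h1")
  pr <- derive_priors(list(sigma2_a = 0.5, sigma2_e = 0.5), geno, pi = 0)
  post <- run_bayesc0(geno, phe, pr, chain_length = 4000, burn_in = 800,
                      seed = 5)
  expect_lt(abs(post$h2_q - 0.5), 0.1)
  # permuted phenotypes carry no signal
  set.seed(93)
  phe$value <- sample(phe$value)
  post0 <- run_bayesc0(geno, phe, pr, chain_length = 4000, burn_in = 800,
                       seed = 6)
  expect_lt(post0$h2_q, 0.1)
})

test_that("BayesB with pi = 0 and a forced common variance matches BayesC0", {
  set.seed(111)
  n <- 300; p <- 100
  geno <- make_geno(n, p, seed = 112)
  y <- rnorm(n) + impute_genotypes(geno) %*% rnorm(p, 0, 0.05)
  phe <- data.frame(id = paste0("a", 1:n), value = as.numeric(y),
                    hatch_class = "h1")
  pr <- derive_priors(list(sigma2_a = 0.3, sigma2_e = 0.7), geno, pi = 0)
  s2u <- 0.003; s2e <- 0.7
  pr_flat <- pr; pr_flat$pi <- 0
  pb <- run_bayesb(geno, phe, pr_flat,
                   chain_length = 6000, burn_in = 1000, seed = 9,
                   fix_variances = TRUE, sigma2_u = s2u, sigma2_e = s2e)
  pc <- run_bayesc0(geno, phe, pr, chain_length = 6000, burn_in = 1000,
                    seed = 9, fix_variances = TRUE,
                    sigma2_u = s2u, sigma2_e = s2e)
  expect_gt(cor(pb$u_hat, pc$u_hat), 0.99)
  expect_lt(abs(pb$h2_q - pc$h2_q), 0.05)
})

test_that("SNP column permutation leaves the posterior unchanged", {
  geno <- make_geno(150, 60, seed = 121)
  set.seed(122)
  phe <- data.frame(id = paste0("a", 1:150),
                    value = rnorm(150), hatch_class = "h1")
  pr <- derive_priors(list(sigma2_a = 0.3, sigma2_e = 0.7), geno)
  post1 <- run_bayesb(geno, phe, pr, chain_length = 500, burn_in = 100,
                      seed = 7)
  perm <- sample(60)
  geno2 <- subset_genotypes(geno, snps = perm)
  post2 <- run_bayesb(geno2, phe, pr, chain_length = 500, burn_in = 100,
                      seed = 7)
  expect_identical(post1$u_hat, post2$u_hat[names(post1$u_hat)])
})

test_that("GEBV computation is an exact, linear inner product", {
  geno <- gw_genotypes(matrix(c(0L, 1L, 2L), 1, 3,
                              dimnames = list("x", NULL)),
                       map = data.frame(snp_id = c("s1", "s2", "s3"),
                                        chrom = 1, pos = 1:3))
  u <- c(s1 = 0.5, s2 = -0.2, s3 = 0.1)
  expect_equal(compute_gebv(geno, u)$gebv, 0.0)
  expect_equal(compute_gebv(geno, u * 0)$gebv, 0)
  expect_equal(compute_gebv(geno, u * 3)$gebv,
               3 * compute_gebv(geno, u)$gebv)
  expect_error(compute_gebv(geno, c(s1 = 1, bad = 2)), "mismatch.*bad")
  expect_error(run_bayesb(geno, data.frame(id = "x", value = 1,
                                           hatch_class = "h"),
                          derive_priors(list(sigma2_a = 1, sigma2_e = 1),
                                        geno),
                          chain_length = 100, burn_in = 200),
               "exceed")
})

test_that("duplicating every record sharpens the residual variance", {
  set.seed(131)
  n <- 200; p <- 80
  geno <- make_geno(n, p, seed = 132)
  y <- rnorm(n)
  phe <- data.frame(id = paste0("a", 1:n), value = y, hatch_class = "h1")
  pr <- derive_priors(list(sigma2_a = 0.3, sigma2_e = 0.7), geno)
  post1 <- run_bayesb(geno, phe, pr, chain_length = 3000, burn_in = 600,
                      seed = 11)
  # duplicate records: same animals twice under new ids
  g2 <- rbind(geno$geno, geno$geno)
  rownames(g2) <- c(paste0("a", 1:n), paste0("b", 1:n))
  geno2 <- gw_genotypes(g2, map = geno$map)
  phe2 <- rbind(phe, transform(phe, id = paste0("b", 1:n)))
  post2 <- run_bayesb(geno2, phe2, pr, chain_length = 3000, burn_in = 600,
                      seed = 11)
  keep <- -seq_len(600)
  rw1 <- sd(post1$chains$var_e[keep]) / mean(post1$chains$var_e[keep])
  rw2 <- sd(post2$chains$var_e[keep]) / mean(post2$chains$var_e[keep])
  expect_lt(rw2, rw1)
  expect_lt(abs(mean(post2$chains$var_e[keep]) -
                  mean(post1$chains$var_e[keep])), 0.15)
})
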