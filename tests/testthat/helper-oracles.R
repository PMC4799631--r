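# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (brute force / Monte Carlo / closed form) and never
# call the code paths they check.

# Gene-dropping estimate of the additive relationship matrix: drop unique
# founder alleles down the pedigree many times and estimate a_xy as twice
# the probability that random alleles from x and y are identical by
# descent.
gene_drop_a <- function(ped, n_drops = 1e5) {
  ped <- ped[order(ped$generation, ped$id), ]
  n <- nrow(ped)
  idx <- seq_len(n)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  al1 <- matrix(0L, n_drops, n)
  al2 <- matrix(0L, n_drops, n)
  next_allele <- 1L
  for (i in idx) {
    if (si[i] == 0L) {
      al1[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_drops) < 0.5
      al1[, i] <- ifelse(pick, al1[, si[i]], al2[, si[i]])
    }
    if (di[i] == 0L) {
      al2[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_drops) < 0.5
      al2[, i] <- ifelse(pick, al1[, di[i]], al2[, di[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in idx) for (j in i:n) {
    phi <- (mean(al1[, i] == al1[, j]) + mean(al1[, i] == al2[, j]) +
            mean(al2[, i] == al1[, j]) + mean(al2[, i] == al2[, j])) / 4
    A[i, j] <- A[j, i] <- 2 * phi # a_xx = 2*phi_xx = 1 + F
  }
  A
}

# Dense multivariate-normal BLUP oracle: beta by GLS, a = Cov(a, y) V^-1
# residual. Equals the MME solution by BLUP theory, computed here without
# any sparse algebra or Henderson rules.
mvn_blup_oracle <- function(A, dataset, sigma2_a, sigma2_e) {
  ids <- rownames(A)
  keep <- as.character(dataset$id)
  Z <- matrix(0, nrow(dataset), length(ids), dimnames = list(NULL, ids))
  Z[cbind(seq_len(nrow(dataset)), match(keep, ids))] <- 1
  cls <- factor(dataset$hatch_class)
  X <- model.matrix(~ 0 + cls)
  V <- Z %*% A %*% t(Z) * sigma2_a + diag(nrow(dataset)) * sigma2_e
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% dataset$value)
  resid <- dataset$value - X %*% beta
  a <- sigma2_a * A %*% t(Z) %*% Vi %*% resid
  list(beta = setNames(as.numeric(beta), levels(cls)),
       ebv = setNames(as.numeric(a), ids))
}

# Joint posterior mean of (beta, u) for ridge regression with known
# variances: the closed form the BayesC0 sampler must reproduce when its
# variances are held fixed.
ridge_oracle <- function(Z, y, cls, sigma2_u, sigma2_e) {
  cls <- factor(cls)
  X <- matrix(0, length(y), nlevels(cls))
  X[cbind(seq_along(y), as.integer(cls))] <- 1
  lam <- sigma2_e / sigma2_u
  p <- ncol(X); q <- ncol(Z)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lam, q)))
  sol <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
  list(beta = sol[seq_len(p)], u = sol[-seq_len(p)])
}

# Random pedigree generator with inbreeding: discrete generations, parents
# drawn from the previous generation (full sibs and repeated sires arise
# naturally, so offspring of related parents are inbred).
random_pedigree <- function(n_founders, n_gens, n_per_gen, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- data.frame(id = seq_len(n_founders), sire = 0L, dam = 0L,
                    generation = 0L,
                    sex = rep_len(c("M", "F"), n_founders))
  for (g in seq_len(n_gens)) {
    prev <- ped[ped$generation == g - 1L, ]
    sires <- prev$id[prev$sex == "M"]
    dams <- prev$id[prev$sex == "F"]
    new <- data.frame(id = max(ped$id) + seq_len(n_per_gen),
                      sire = sample(sires, n_per_gen, replace = TRUE),
                      dam = sample(dams, n_per_gen, replace = TRUE),
                      generation = g,
                      sex = sample(rep_len(c("M", "F"), n_per_gen)))
    ped <- rbind(ped, new)
  }
  ped
}

# Mean r2 (squared allelic correlation) between locus pairs in a distance
# window, computed from haplotypes.
mean_r2_in_window <- function(haps, min_d, max_d, max_pairs = 2000) {
  H <- rbind(haps$H1, haps$H2)
  map <- haps$map
  pairs <- list()
  for (c in unique(map$chrom)) {
    loci <- which(map$chrom == c)
    if (length(loci) < 2) next
    cmb <- t(combn(loci, 2))
    d <- abs(map$pos[cmb[, 1]] - map$pos[cmb[, 2]])
    ok <- d >= min_d & d < max_d
    if (any(ok)) pairs[[length(pairs) + 1L]] <- cmb[ok, , drop = FALSE]
  }
  if (!length(pairs)) return(NA_real_)
  pairs <- do.call(rbind, pairs)
  if (nrow(pairs) > max_pairs)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  r2 <- apply(pairs, 1, function(ij) {
    x <- H[, ij[1]]; y <- H[, ij[2]]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)^2
  })
  mean(r2, na.rm = TRUE)
}
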