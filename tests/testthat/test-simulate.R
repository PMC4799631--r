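# Population simulator: LD structure, QTL scaling, gamete formation,
# phenotype model, selection, and the end-to-end generator contracts.

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_chrom = 0), "chromosome")
  expect_error(sim_config(n_qtl = 0, target_h2 = 0.5), "n_qtl")
  expect_error(sim_config(target_h2 = 1.2), "target_h2")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_males_selected = 700,
                          n_offspring_per_gen = 600), "selected counts")
})

test_that("founders without shared history are in linkage equilibrium", {
  cfg <- small_cfg(seed = 11, n_burnin_gens = 0, n_founders = 200,
                   n_snps = 150, n_chrom = 2)
  set.seed(1)
  haps <- simulate_founder_haplotypes(cfg)
  r2_adj <- mean_r2_in_window(haps, 0, 0.01)
  # expected E[r2] ~ 1/(2n) for independent draws over 400 haplotypes
  expect_lt(r2_adj, 0.02)
})

test_that("burn-in generates LD that decays with map distance", {
  # averaged over replicate simulations; bins 0-1, 1-5, 5-25 cM
  r2 <- matrix(NA_real_, 20, 3)
  for (r in 1:20) {
    cfg <- small_cfg(seed = 500 + r, n_founders = 50, n_burnin_gens = 60,
                     n_snps = 120, n_chrom = 2)
    set.seed(500 + r)
    haps <- simulate_founder_haplotypes(cfg, n_extra_loci = 0)
    r2[r, 1] <- mean_r2_in_window(haps, 0, 0.01)
    r2[r, 2] <- mean_r2_in_window(haps, 0.01, 0.05)
    r2[r, 3] <- mean_r2_in_window(haps, 0.05, 0.25)
  }
  m <- colMeans(r2, na.rm = TRUE)
  expect_gt(m[1], m[2])
  expect_gt(m[2], m[3])
  # close pairs carry much more LD than distant ones
  expect_gt(m[1], 2 * m[3])
})

test_that("drifted-out loci are dropped so no monomorphic SNP survives", {
  cfg <- small_cfg(seed = 21, n_founders = 20, n_burnin_gens = 60,
                   n_snps = 100, n_chrom = 2)
  set.seed(21)
  haps <- simulate_founder_haplotypes(cfg)
  freq <- colMeans(haps$H1 + haps$H2) / 2
  expect_true(all(freq > 0 & freq < 1))
  # strong drift in a population of 20 must have fixed some loci
  expect_lt(ncol(haps$H1), 100 + cfg$n_qtl + ceiling(0.3 * 140))
})

test_that("QTL effects are rescaled to the target heritability", {
  cfg <- small_cfg(seed = 31, n_founders = 300, n_burnin_gens = 0,
                   target_h2 = c(a = 0.5, b = 0.2))
  set.seed(31)
  haps <- simulate_founder_haplotypes(cfg)
  arch <- assign_qtl_effects(cfg, haps)
  zq <- haps$H1[, arch$qtl] + haps$H2[, arch$qtl]
  v <- apply(zq %*% arch$effects, 2, var)
  expect_equal(unname(v), c(0.5, 0.2), tolerance = 1e-10)
  # single-locus closed form: one QTL of effect alpha at frequency p gives
  # additive variance ~ 2p(1-p)alpha^2 (HWE founders)
  cfg1 <- small_cfg(seed = 32, n_founders = 2000, n_burnin_gens = 0,
                    n_qtl = 1, target_h2 = c(a = 0.3))
  set.seed(32)
  haps1 <- simulate_founder_haplotypes(cfg1)
  arch1 <- assign_qtl_effects(cfg1, haps1)
  p <- mean(haps1$H1[, arch1$qtl] + haps1$H2[, arch1$qtl]) / 2
  expect_equal(unname(2 * p * (1 - p) * arch1$effects[1, 1]^2), 0.3,
               tolerance = 0.05)
})

test_that("gametes recombine at the expected rate and obey dosage rules", {
  cfg <- small_cfg(seed = 41, n_chrom = 1, chrom_length_morgans = 1,
                   n_snps = 300, n_founders = 10, n_burnin_gens = 0)
  set.seed(41)
  haps <- simulate_founder_haplotypes(cfg, n_extra_loci = 0)
  # count phase switches along a dense map using distinguishable haplotypes
  n_loci <- ncol(haps$H1)
  h1 <- rep(0L, n_loci); h2 <- rep(1L, n_loci)
  sm <- genwin:::split_map(haps$map, 1L, 1)
  set.seed(42)
  switches <- replicate(2000, sum(diff(genwin:::make_gamete(h1, h2, sm)) != 0))
  expect_equal(mean(switches), 1.0, tolerance = 0.1)

  # zero-length chromosome: every gamete is a full parental copy
  cfg0 <- small_cfg(seed = 43, n_chrom = 1, chrom_length_morgans = 0,
                    n_founders = 10, n_burnin_gens = 0, n_snps = 50)
  set.seed(43)
  haps0 <- simulate_founder_haplotypes(cfg0, n_extra_loci = 0)
  sm0 <- genwin:::split_map(haps0$map, 1L, 0)
  h1 <- haps0$H1[1, ]; h2 <- haps0$H2[1, ]
  for (i in 1:20) {
    g <- genwin:::make_gamete(h1, h2, sm0)
    expect_true(identical(g, h1) || identical(g, h2))
  }
})

test_that("offspring dosages are consistent with parental gametes", {
  cfg <- small_cfg(seed = 51)
  set.seed(51)
  haps <- simulate_founder_haplotypes(cfg)
  haps$ids <- seq_len(nrow(haps$H1))
  off <- breed_generation(sires = 1:3, dams = 4:9, haps, cfg,
                          n_offspring = 30)
  g <- off$haps$H1 + off$haps$H2
  expect_true(all(g %in% 0:2))
  expect_true(all(off$haps$H1 %in% 0:1))
  # parent bookkeeping: every offspring has a recorded sire and dam
  expect_true(all(off$pedigree$sire %in% 1:3))
  expect_true(all(off$pedigree$dam %in% 4:9))
  expect_error(breed_generation(integer(0), 4:9, haps, cfg), "sire")
})

test_that("phenotypes follow y = hatch + BV + e with the stated variances", {
  set.seed(61)
  n <- 4000
  bv <- matrix(rnorm(n, 0, sqrt(0.5)), ncol = 1,
               dimnames = list(NULL, "tt"))
  he <- matrix(c(1, -1), 2, 1, dimnames = list(c("A", "B"), "tt"))
  cls <- rep(c("A", "B"), length.out = n)
  phe <- simulate_phenotypes(bv, cls, he, c(tt = 0.5))
  expect_equal(mean(phe$value[phe$hatch_class == "A"]) -
                 mean(phe$value[phe$hatch_class == "B"]), 2,
               tolerance = 0.15)
  # h2 -> 1 limit: adjusted phenotype equals the breeding value
  phe1 <- simulate_phenotypes(bv, cls, he, c(tt = 1))
  adj <- phe1$value - he[phe1$hatch_class, 1]
  expect_equal(cor(adj, bv[, 1]), 1, tolerance = 1e-12)
  expect_error(simulate_phenotypes(bv, cls, he, c(tt = 1.5)), "h2")
})

test_that("midparent-offspring regression recovers h2", {
  # classical quantitative-genetics oracle: slope of offspring phenotype on
  # midparent phenotype estimates h2
  cfg <- small_cfg(seed = 71, n_founders = 200, n_burnin_gens = 10,
                   n_gens = 1, n_offspring_per_gen = 2000,
                   n_males_selected = 50, n_females_selected = 100,
                   selection_mode = "random", phenotype_both_sexes = TRUE,
                   hatch_effect_sd = 0, n_hatches_per_gen = 1)
  pop <- simulate_population(cfg)
  phe <- trait_data(pop)
  v <- setNames(phe$value, phe$id)
  off <- pop$pedigree[pop$pedigree$generation == 1, ]
  mid <- (v[as.character(off$sire)] + v[as.character(off$dam)]) / 2
  slope <- coef(lm(v[as.character(off$id)] ~ mid))[2]
  expect_lt(abs(unname(slope) - 0.5), 0.1)
})

test_that("selection ranks candidates and respects ties and modes", {
  cand <- data.frame(id = c(3L, 1L, 2L, 4L), sex = c("M", "M", "F", "F"))
  crit <- c(`3` = 1, `1` = 1, `2` = 5, `4` = 9)
  sel <- select_parents(cand, 1, 2, criterion = crit)
  expect_identical(sel$sires, 1L) # tie broken by id order
  expect_identical(sel$dams, c(4L, 2L))
  expect_error(select_parents(cand, 3, 1, criterion = crit), "candidates")
  set.seed(9); a <- select_parents(cand, 1, 1, mode = "random")
  set.seed(9); b <- select_parents(cand, 1, 1, mode = "random")
  expect_identical(a, b)
})

test_that("phenotypic selection yields gain near the breeder's equation", {
  # i * h2 * sigma_P per generation; proportion selected 30/100 per sex
  # pooled => i ~ 1.4 on the mid-parent average
  gains <- replicate(5, {
    seed <- sample.int(1e6, 1)
    cfg <- small_cfg(seed = seed, n_founders = 100, n_burnin_gens = 5,
                     n_gens = 3, n_offspring_per_gen = 300,
                     n_males_selected = 30, n_females_selected = 30,
                     selection_mode = "phenotype",
                     phenotype_both_sexes = TRUE, hatch_effect_sd = 0,
                     n_hatches_per_gen = 1)
    pop <- simulate_population(cfg)
    bv_mean <- tapply(pop$true_bv[, 1],
                      pop$pedigree$generation[match(rownames(pop$true_bv),
                                                    pop$pedigree$id)],
                      mean)
    mean(diff(bv_mean[-1])) # per-generation gain after the first round
  })
  i <- 1.159 # selection intensity at p = 0.3
  expected <- i * 0.5 * 1 # h2 = 0.5, sigma_P = 1
  expect_equal(mean(gains), expected, tolerance = 0.3 * expected)
})

test_that("ebv selection raises mean true breeding value across generations", {
  set.seed(81)
  up <- replicate(3, {
    cfg <- small_cfg(seed = sample.int(1e6, 1), selection_mode = "ebv",
                     n_gens = 3)
    pop <- simulate_population(cfg)
    g <- pop$pedigree$generation[match(rownames(pop$true_bv),
                                       pop$pedigree$id)]
    bv_mean <- tapply(pop$true_bv[, 1], g, mean)
    all(diff(bv_mean) > 0)
  })
  expect_gte(mean(up), 2 / 3)
})

test_that("the end-to-end generator honours its output contracts", {
  cfg <- small_cfg(seed = 91, missing_rate = 0.1, genotype_error_rate = 0)
  pop <- simulate_population(cfg)
  # missingness close to nominal
  expect_equal(mean(is.na(pop$genotypes$geno)), 0.10, tolerance = 0.01)
  # no Mendelian inconsistencies when the error channel is off
  rates <- genwin:::mendelian_rates(pop$genotypes$geno, pop$pedigree)
  expect_true(all(rates == 0))
  # determinism: same seed twice gives identical output
  pop2 <- simulate_population(cfg)
  expect_identical(pop$pedigree, pop2$pedigree)
  expect_identical(pop$genotypes$geno, pop2$genotypes$geno)
  expect_identical(pop$phenotypes, pop2$phenotypes)
  # pedigree structure: offspring generation = parent generation + 1,
  # phenotyped animals all in the pedigree, hatch nested in generation
  ped <- pop$pedigree
  par_gen <- ped$generation[match(ped$sire, ped$id)]
  expect_true(all(ped$generation[ped$sire > 0] == par_gen[ped$sire > 0] + 1))
  expect_true(all(pop$phenotypes$id %in% ped$id))
  expect_true(all(startsWith(pop$phenotypes$hatch_class,
                             paste0("G", pop$phenotypes$generation))))
  # allele frequency invariant: p equals column mean / 2 over non-missing
  expect_equal(pop$genotypes$p,
               colMeans(pop$genotypes$geno, na.rm = TRUE) / 2)
})
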