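# SNP QC, training/validation design, accuracy statistic, sweep and
# scenario engines.

test_that("QC threshold semantics are strict exactly as specified", {
  # 100 animals; engineer call rate, MAF and Mendelian rate around the
  # thresholds
  set.seed(33)
  n <- 100
  g <- sapply(rep(0.3, 6), function(q) rbinom(n, 2, q))
  colnames(g) <- paste0("s", 1:6)
  g[1:6, 1] <- NA              # call rate 0.94 -> removed
  g[1:5, 2] <- NA              # call rate 0.95 -> kept
  g[, 3] <- 0L; g[1:4, 3] <- 1L                 # MAF 0.02 -> removed
  g[, 4] <- 0L; g[1:5, 4] <- 1L                 # MAF 0.025 -> kept
  geno <- gw_genotypes(g, ids = paste0("a", 1:n))
  qc <- qc_filter_snps(geno, ped = NULL)
  expect_false("s1" %in% colnames(qc$genotypes$geno))
  expect_true("s2" %in% colnames(qc$genotypes$geno))
  expect_false("s3" %in% colnames(qc$genotypes$geno))
  expect_true("s4" %in% colnames(qc$genotypes$geno))
  expect_identical(unname(qc$removed["call_rate"]), 1L)
  expect_identical(unname(qc$removed["maf"]), 1L)
})

test_that("Mendelian filter uses informative trios and the printed bound", {
  # three trios; SNP "bad": AA x AA -> aa in 1 of 3 informative trios
  # (rate 0.33 > 0.05, removed); SNP "mid": rate exactly 0 -> kept
  ped <- data.frame(id = c(1:6, 7:9),
                    sire = c(rep(0L, 6), 1L, 3L, 5L),
                    dam = c(rep(0L, 6), 2L, 4L, 6L),
                    generation = c(rep(0L, 6), 1L, 1L, 1L))
  g <- rbind(matrix(0L, 6, 2), matrix(0L, 3, 2))
  rownames(g) <- as.character(1:9)
  colnames(g) <- c("bad", "good")
  g[, "bad"] <- c(0L, 0L, 0L, 0L, 0L, 0L, 2L, 0L, 0L) # offspring 7 impossible
  # make both columns polymorphic overall so MAF keeps them
  g <- rbind(g, matrix(1L, 30, 2, dimnames = list(as.character(10:39), NULL)))
  geno <- gw_genotypes(g, ids = rownames(g))
  rates <- genwin:::mendelian_rates(geno$geno, ped)
  expect_equal(unname(rates), c(1 / 3, 0))
  qc <- qc_filter_snps(geno, ped)
  expect_identical(colnames(qc$genotypes$geno), "good")
  # re-running QC on filtered output removes nothing
  qc2 <- qc_filter_snps(qc$genotypes, ped)
  expect_true(all(qc2$removed == 0))
  # per-filter counts add up to the total removed
  expect_identical(sum(qc$removed), 1L)
})

test_that("training windows precede validation and respect the caps", {
  pop <- small_pop()
  d <- make_training_sets(pop, validation_gen = 4, k = 2,
                          method = "bayesb")
  expect_identical(d$train_gens, 2:3)
  ped <- pop$pedigree
  expect_true(all(ped$generation[match(d$train_ids, ped$id)] %in% 2:3))
  expect_true(all(ped$generation[match(d$val_ids, ped$id)] == 4))
  expect_true(all(ped$sex[match(d$val_ids, ped$id)] == "F"))
  expect_error(make_training_sets(pop, 4, 0), "k")
  expect_error(make_training_sets(pop, 4, 9, method = "bayesb"),
               "cap of 8")
  expect_error(make_training_sets(pop, 4, 11, method = "pblup_full"),
               "cap of 10")
  expect_error(make_training_sets(pop, 4, 5, method = "pblup_full"),
               "available")
})

test_that("the accuracy statistic behaves at its analytic anchors", {
  set.seed(44)
  n <- 500
  cls <- sample(c("c1", "c2"), n, TRUE)
  eff <- c(c1 = 0.5, c2 = -0.5)
  y_adj_true <- rnorm(n)
  phe <- data.frame(id = seq_len(n), value = y_adj_true + eff[cls],
                    hatch_class = cls)
  # EBV identical to adjusted phenotypes at h2 = 1: accuracy exactly 1
  acc <- prediction_accuracy(data.frame(id = seq_len(n), ebv = y_adj_true),
                             phe, eff, h2 = 1)
  expect_equal(acc$accuracy, 1)
  expect_equal(acc$n, n)
  # independent EBV: near zero
  acc0 <- prediction_accuracy(data.frame(id = seq_len(n),
                                         ebv = rnorm(n)), phe, eff, 1)
  expect_lt(abs(acc0$accuracy), 2 / sqrt(n) * 2)
  # affine invariance
  acc2 <- prediction_accuracy(data.frame(id = seq_len(n),
                                         ebv = 3 * y_adj_true + 7),
                              phe, eff, 1)
  expect_equal(acc2$accuracy, acc$accuracy)
  expect_error(prediction_accuracy(data.frame(id = 1:2, ebv = c(1, 1)),
                                   phe[1:2, ], eff, 1), "undefined")
})

test_that("true breeding values score near-perfect standardized accuracy", {
  set.seed(45)
  n <- 2000; h2 <- 0.5
  bv <- rnorm(n, 0, sqrt(h2))
  cls <- sample(c("c1", "c2"), n, TRUE)
  eff <- c(c1 = 1, c2 = -1)
  y <- bv + eff[cls] + rnorm(n, 0, sqrt(1 - h2))
  phe <- data.frame(id = seq_len(n), value = y, hatch_class = cls)
  # corr(BV, y_adj) ~ sqrt(h2); dividing by sqrt(h2) gives ~ 1
  acc <- prediction_accuracy(data.frame(id = seq_len(n), ebv = bv),
                             phe, eff, h2)
  expect_equal(acc$accuracy, 1, tolerance = 0.05)
})

test_that("the sweep emits one record per design and is order-invariant", {
  pop <- cached_pop("sweep", small_cfg(seed = 161, n_gens = 5,
                                       target_h2 = c(a = 0.5, b = 0.3)))
  sw <- run_generation_sweep(pop, validation_gens = 4:5, k_range = 1:2,
                             methods = c("pblup_full", "bayesb"),
                             chain_length = 600, burn_in = 100, seed = 2)
  expect_identical(nrow(sw), 2L * 2L * 2L * 2L) # traits x gens x k x methods
  expect_length(attr(sw, "failures"), 0)
  expect_true(all(is.finite(sw$accuracy)))
  # processing traits in the other order changes nothing
  sw2 <- run_generation_sweep(pop, traits = c("b", "a"),
                              validation_gens = 4:5, k_range = 1:2,
                              methods = c("pblup_full", "bayesb"),
                              chain_length = 600, burn_in = 100, seed = 2)
  key <- function(d) d[order(d$trait, d$method, d$validation_gen, d$k), ]
  expect_equal(key(sw)$accuracy, key(sw2)$accuracy)
})

test_that("scenario engine samples within generations and is reproducible", {
  pop <- cached_pop("sweep", small_cfg(seed = 161, n_gens = 5,
                                       target_h2 = c(a = 0.5, b = 0.3)))
  scen <- list(near = c(`4` = 30), far = c(`2` = 15, `3` = 15))
  res <- run_size_composition_scenarios(pop, trait = "a", scen,
                                        validation_gen = 5,
                                        n_replicates = 2,
                                        chain_length = 600, burn_in = 100,
                                        seed = 4)
  expect_identical(nrow(res), 2L)
  expect_identical(res$n_train, c(30, 30))
  expect_identical(res$n_gens, c(1L, 2L))
  res2 <- run_size_composition_scenarios(pop, trait = "a", scen,
                                         validation_gen = 5,
                                         n_replicates = 2,
                                         chain_length = 600, burn_in = 100,
                                         seed = 4)
  expect_identical(res, res2)
  expect_error(run_size_composition_scenarios(pop, "a",
                                              list(c(`4` = 10000)),
                                              validation_gen = 5,
                                              n_replicates = 1,
                                              chain_length = 600,
                                              burn_in = 100, seed = 4),
               "eligible")
})
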