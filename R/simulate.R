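# Population simulator: founder LD via random-mating burn-in, gamete
# formation under the Haldane model, truncation selection, phenotypes with
# hatch-within-generation fixed effects, and genotyping with missingness and
# error injection.

# ---- genetic map ----------------------------------------------------------

# Loci positions: uniform on each chromosome, sorted. `n_loci` is the total
# count across chromosomes (split as evenly as possible).
make_genetic_map <- function(n_loci, n_chrom, chrom_len) {
  per <- rep(n_loci %/% n_chrom, n_chrom)
  extra <- n_loci %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  chrom <- rep(seq_len(n_chrom), per)
  pos <- unlist(lapply(per, function(k) sort(runif(k, 0, chrom_len))),
                use.names = FALSE)
  data.frame(locus = seq_len(n_loci), chrom = chrom, pos = pos)
}

# Precompute per-chromosome locus indices for fast meiosis.
split_map <- function(map, n_chrom, chrom_len) {
  list(idx = split(map$locus, factor(map$chrom, levels = seq_len(n_chrom))),
       pos = split(map$pos, factor(map$chrom, levels = seq_len(n_chrom))),
       len = rep(chrom_len, n_chrom))
}

# One recombinant gamete from a parent's two haplotypes. Crossover counts are
# Poisson(chromosome length in Morgans) with uniform positions (Haldane, no
# interference); the starting phase of each chromosome is random.
make_gamete <- function(h1, h2, sm) {
  g <- h2 # phase 1 default, overwritten where phase 0
  for (c in seq_along(sm$idx)) {
    idx <- sm$idx[[c]]
    if (length(idx) == 0L) next
    pos <- sm$pos[[c]]
    nxo <- rpois(1L, sm$len[c])
    phase0 <- runif(1L) < 0.5
    if (nxo > 0L) {
      xo <- sort.int(runif(nxo, 0, sm$len[c]))
      ph <- (as.integer(phase0) + findInterval(pos, xo)) %% 2L
      take1 <- ph == 0L
    } else {
      take1 <- rep(phase0, length(idx))
    }
    gi <- h2[idx]
    gi[take1] <- h1[idx][take1]
    g[idx] <- gi
  }
  g
}

# ---- founders -------------------------------------------------------------

#' Simulate founder haplotypes with linkage disequilibrium
#'
#' Creates an initial panel of biallelic loci (allele frequencies uniform on
#' `(0.1, 0.9)`), then runs `n_burnin_gens` generations of discrete random
#' mating in a population of `n_founders` so that drift in the finite
#' population builds up LD that decays with map distance. Loci that drift to
#' fixation during the burn-in are dropped, so the returned panel contains no
#' monomorphic locus; to compensate, 30% more loci than requested are seeded.
#'
#' @param cfg A [sim_config()] object.
#' @param n_extra_loci Number of loci to simulate beyond `n_snps` (defaults
#'   to `n_qtl` plus a 30% drift margin).
#' @return An object of class `gw_haplotypes`: list with integer 0/1 matrices
#'   `H1`, `H2` (animals x loci), a `map` data frame (`locus`, `chrom`,
#'   `pos` in Morgans) and animal `ids`.
#' @export
simulate_founder_haplotypes <- function(cfg, n_extra_loci = NULL) {
  stopifnot(inherits(cfg, "gw_sim_config"))
  if (cfg$n_chrom < 1L || cfg$n_snps < 1L)
    stop_genwin("configuration error: zero chromosomes or zero SNPs")
  n_extra_loci <- n_extra_loci %||%
    (cfg$n_qtl + ceiling(0.3 * (cfg$n_snps + cfg$n_qtl)))
  n_loci <- cfg$n_snps + n_extra_loci
  map <- make_genetic_map(n_loci, cfg$n_chrom, cfg$chrom_length_morgans)
  sm <- split_map(map, cfg$n_chrom, cfg$chrom_length_morgans)
  n <- cfg$n_founders

  p0 <- runif(n_loci, 0.1, 0.9)
  H1 <- matrix(as.integer(runif(n * n_loci) < rep(p0, each = n)), n, n_loci)
  H2 <- matrix(as.integer(runif(n * n_loci) < rep(p0, each = n)), n, n_loci)

  if (cfg$n_burnin_gens > 0L) {
    for (g in seq_len(cfg$n_burnin_gens)) {
      N1 <- H1; N2 <- H2
      for (i in seq_len(n)) {
        par <- sample.int(n, 2L) # two distinct random parents
        N1[i, ] <- make_gamete(H1[par[1L], ], H2[par[1L], ], sm)
        N2[i, ] <- make_gamete(H1[par[2L], ], H2[par[2L], ], sm)
      }
      H1 <- N1; H2 <- N2
    }
  }

  freq <- (colSums(H1) + colSums(H2)) / (2 * n)
  poly <- freq > 0 & freq < 1
  if (!any(poly))
    stop_genwin("all loci fixed during burn-in; increase n_founders or loci")
  structure(list(H1 = H1[, poly, drop = FALSE],
                 H2 = H2[, poly, drop = FALSE],
                 map = transform(map[poly, ], locus = seq_len(sum(poly))),
                 ids = seq_len(n)),
            class = "gw_haplotypes")
}

#' @export
print.gw_haplotypes <- function(x, ...) {
  cat(sprintf("<gw_haplotypes> %d animals x %d polymorphic loci on %d chromosome(s)\n",
              nrow(x$H1), ncol(x$H1), length(unique(x$map$chrom))))
  invisible(x)
}

# Genotype dosages (0/1/2) of a haplotype set.
hap_dosage <- function(haps, loci = NULL) {
  if (is.null(loci)) haps$H1 + haps$H2
  else haps$H1[, loci, drop = FALSE] + haps$H2[, loci, drop = FALSE]
}

# ---- QTL effects ----------------------------------------------------------

#' Assign additive QTL effects scaled to a target heritability
#'
#' Chooses `n_qtl` QTL among the simulated polymorphic loci (off the SNP
#' panel by default, so markers tag them only through LD), draws one standard
#' normal effect per QTL per trait, and rescales the effects so that the
#' variance of true breeding values across the founder animals equals
#' `target_h2` of a unit phenotypic variance.
#'
#' @param cfg A [sim_config()] object.
#' @param haps Founder `gw_haplotypes`.
#' @return A list of class `gw_trait_arch`: `qtl` (locus indices), `panel`
#'   (locus indices of the SNP panel), `effects` (n_qtl x n_traits matrix),
#'   `bv_founder_mean` (per trait), and `var_bv` (realized founder
#'   breeding-value variance per trait, equal to `target_h2` by
#'   construction).
#' @export
assign_qtl_effects <- function(cfg, haps) {
  stopifnot(inherits(cfg, "gw_sim_config"), inherits(haps, "gw_haplotypes"))
  h2 <- cfg$target_h2
  n_traits <- length(h2)
  n_loci <- ncol(haps$H1)
  if (cfg$n_qtl == 0L && any(h2 > 0))
    stop_genwin("n_qtl = 0 cannot carry target_h2 > 0")
  if (cfg$n_qtl + (!cfg$qtl_on_panel) * cfg$n_snps > n_loci &&
      !cfg$qtl_on_panel && cfg$n_qtl + cfg$n_snps > n_loci) {
    # fewer polymorphic loci than requested: shrink the panel, keep the QTL
    if (cfg$n_qtl >= n_loci)
      stop_genwin("not enough polymorphic loci for ", cfg$n_qtl, " QTL")
  }
  if (cfg$qtl_on_panel) {
    panel <- sort(sample.int(n_loci, min(cfg$n_snps, n_loci)))
    qtl <- sort(sample(panel, cfg$n_qtl))
  } else {
    qtl <- sort(sample.int(n_loci, cfg$n_qtl))
    rest <- setdiff(seq_len(n_loci), qtl)
    panel <- sort(sample(rest, min(cfg$n_snps, length(rest))))
  }
  effects <- matrix(rnorm(cfg$n_qtl * n_traits), cfg$n_qtl, n_traits,
                    dimnames = list(NULL, names(h2)))
  zq <- hap_dosage(haps, qtl)
  for (t in seq_len(n_traits)) {
    v <- var(as.vector(zq %*% effects[, t]))
    effects[, t] <- if (v > 0) effects[, t] * sqrt(h2[t] / v) else 0
  }
  bv <- zq %*% effects
  structure(list(qtl = qtl, panel = panel, effects = effects,
                 bv_founder_mean = colMeans(bv),
                 var_bv = apply(bv, 2, var)),
            class = "gw_trait_arch")
}

# True breeding values (centered at the founder mean) for a haplotype set.
true_bv <- function(haps, arch) {
  bv <- hap_dosage(haps, arch$qtl) %*% arch$effects
  sweep(bv, 2, arch$bv_founder_mean)
}

# ---- breeding -------------------------------------------------------------

#' Breed one generation of offspring from selected parents
#'
#' Each offspring receives one recombinant gamete from its sire and one from
#' its dam (Poisson crossover counts, uniform positions, no interference: Poisson crossover counts, uniform
#' positions, no interference). Dams are assigned to sires round-robin
#' (`n_dams/n_sires` dams per sire) and offspring are divided as equally as
#' possible among dams.
#'
#' @param sires,dams Integer indices (rows of `haps`) of selected parents.
#' @param haps `gw_haplotypes` of the parental generation candidates.
#' @param cfg A [sim_config()] object (supplies `n_offspring_per_gen`).
#' @param n_offspring Override for the number of offspring.
#' @return A list: offspring `gw_haplotypes` and a `pedigree` data frame
#'   (`sire`, `dam` as indices into `haps$ids`).
#' @export
breed_generation <- function(sires, dams, haps, cfg, n_offspring = NULL) {
  if (length(sires) < 1L || length(dams) < 1L)
    stop_genwin("breed_generation: need at least one sire and one dam")
  n_off <- as.integer(n_offspring %||% cfg$n_offspring_per_gen)
  sm <- split_map(haps$map, max(haps$map$chrom), cfg$chrom_length_morgans)
  # round-robin dam-to-sire assignment, offspring split equally across dams
  dam_of_off <- rep_len(dams, n_off)
  sire_of_dam <- rep_len(sires, length(dams))
  names(sire_of_dam) <- as.character(dams)
  sire_of_off <- sire_of_dam[as.character(dam_of_off)]
  n_loci <- ncol(haps$H1)
  H1 <- matrix(0L, n_off, n_loci)
  H2 <- matrix(0L, n_off, n_loci)
  row_of <- match(haps$ids, haps$ids) # identity; ids are row-aligned
  for (i in seq_len(n_off)) {
    s <- match(sire_of_off[i], haps$ids)
    d <- match(dam_of_off[i], haps$ids)
    H1[i, ] <- make_gamete(haps$H1[s, ], haps$H2[s, ], sm)
    H2[i, ] <- make_gamete(haps$H1[d, ], haps$H2[d, ], sm)
  }
  list(haps = structure(list(H1 = H1, H2 = H2, map = haps$map,
                             ids = seq_len(n_off)),
                        class = "gw_haplotypes"),
       pedigree = data.frame(sire = unname(sire_of_off), dam = dam_of_off))
}

# ---- phenotypes -----------------------------------------------------------

#' Simulate phenotypes from true breeding values
#'
#' `y = hatch effect + BV + e` with `e ~ N(0, (1 - h2)/h2 * var_bv_target)`;
#' since breeding values are scaled so that their founder variance is `h2`
#' of a unit phenotypic variance, the residual variance is simply `1 - h2`.
#' `h2 = 1` gives noise-free phenotypes (simulation-only limit).
#'
#' @param bv Numeric matrix of true breeding values (animals x traits) with
#'   trait column names, as produced by the simulator.
#' @param hatch_class Character vector of hatch-within-generation class
#'   labels, one per animal.
#' @param hatch_effects Named numeric matrix (classes x traits) of fixed
#'   hatch effects; missing classes get effect 0.
#' @param h2 Per-trait heritability vector in `(0, 1]`.
#' @return Data frame with one row per animal x trait: `animal` (row index),
#'   `trait`, `value`, `hatch_class`.
#' @export
simulate_phenotypes <- function(bv, hatch_class, hatch_effects, h2) {
  if (any(h2 <= 0) || any(h2 > 1))
    stop_genwin("h2 must lie in (0, 1]")
  bv <- as.matrix(bv)
  traits <- colnames(bv) %||% names(h2)
  n <- nrow(bv)
  out <- vector("list", length(traits))
  for (t in seq_along(traits)) {
    he <- hatch_effects[match(hatch_class, rownames(hatch_effects)), traits[t]]
    he[is.na(he)] <- 0
    sde <- sqrt(max(0, 1 - h2[t]))
    out[[t]] <- data.frame(animal = seq_len(n), trait = traits[t],
                           value = he + bv[, t] + rnorm(n, 0, sde),
                           hatch_class = hatch_class,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- selection ------------------------------------------------------------

#' Truncation-select parents within each sex
#'
#' Ranks candidates by the supplied criterion within each sex and keeps the
#' top `n_males`/`n_females`; ties are broken by id order (ascending), and
#' `mode = "random"` ignores the criterion.
#'
#' @param candidates Data frame with columns `id` and `sex` (`"M"`/`"F"`).
#' @param n_males,n_females Numbers of each sex to keep.
#' @param criterion Named numeric vector (names = ids); required unless
#'   `mode = "random"`.
#' @param mode `"criterion"` or `"random"`.
#' @return List with integer vectors `sires` and `dams`.
#' @export
select_parents <- function(candidates, n_males, n_females,
                           criterion = NULL, mode = c("criterion", "random")) {
  mode <- match.arg(mode)
  pick <- function(sub, k) {
    if (nrow(sub) < k)
      stop_genwin("select_parents: only ", nrow(sub),
                  " candidates for ", k, " selections")
    if (mode == "random") return(sub$id[sample.int(nrow(sub), k)])
    crit <- criterion[as.character(sub$id)]
    if (anyNA(crit))
      stop_genwin("select_parents: criterion missing for some candidates")
    sub$id[order(-crit, sub$id)][seq_len(k)]
  }
  list(sires = pick(candidates[candidates$sex == "M", , drop = FALSE], n_males),
       dams = pick(candidates[candidates$sex == "F", , drop = FALSE], n_females))
}

# ---- end-to-end population ------------------------------------------------

#' Simulate a complete multi-generation breeding population
#'
#' Runs the full generator: burn-in founders, QTL assignment, `n_gens`
#' recorded generations bred from truncation-selected parents, phenotypes
#' with hatch-within-generation effects, and genotyping of all selected
#' parents plus `genotyped_fraction` of the females of each recorded
#' generation, with missing calls and genotyping errors injected afterwards
#' (so QC filters see realistic data). True breeding values are retained for
#' validation.
#'
#' @param cfg A [sim_config()] object.
#' @return An object of class `gw_population`: list with `pedigree` (id,
#'   sire, dam, generation, sex, hatch_class; 0 = unknown parent),
#'   `phenotypes` (id, trait, value, hatch_class, generation), `genotypes`
#'   (a `gw_genotypes` object over the SNP panel), `true_bv` (matrix, all
#'   animals x traits), `qtl` (map + effects of the causal loci),
#'   `hatch_effects`, and `cfg`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "gw_sim_config"))
  set.seed(substream_seed(cfg$seed, "founders"))
  haps <- simulate_founder_haplotypes(cfg)
  set.seed(substream_seed(cfg$seed, "architecture"))
  arch <- assign_qtl_effects(cfg, haps)
  h2 <- cfg$target_h2
  traits <- names(h2)

  n0 <- cfg$n_founders
  ped <- data.frame(id = seq_len(n0), sire = 0L, dam = 0L, generation = 0L,
                    sex = NA_character_, hatch = NA_integer_,
                    stringsAsFactors = FALSE)
  set.seed(substream_seed(cfg$seed, "founder-labels"))
  # founders get an exactly balanced sex ratio so selection is feasible
  ped$sex <- sample(rep_len(c("F", "M"), n0))
  ped$hatch <- sample.int(cfg$n_hatches_per_gen, n0, replace = TRUE)

  # hatch-class effects, one per (generation, hatch, trait)
  set.seed(substream_seed(cfg$seed, "hatch-effects"))
  classes <- as.vector(outer(seq_len(cfg$n_hatches_per_gen),
                             0:cfg$n_gens,
                             function(h, g) sprintf("G%d_H%d", g, h)))
  hatch_eff <- matrix(rnorm(length(classes) * length(traits),
                            0, cfg$hatch_effect_sd),
                      length(classes), length(traits),
                      dimnames = list(classes, traits))

  bv_all <- true_bv(haps, arch)
  rownames(bv_all) <- as.character(ped$id)
  hclass <- sprintf("G%d_H%d", ped$generation, ped$hatch)

  set.seed(substream_seed(cfg$seed, "phenotypes-G0"))
  phe_int <- simulate_phenotypes(bv_all, hclass, hatch_eff, h2)
  phe_int$id <- ped$id[phe_int$animal]
  phe_int$generation <- 0L
  phe_list <- list(phe_int)

  gen_haps <- haps             # haplotypes of current candidate generation
  gen_ids <- ped$id            # ids aligned to gen_haps rows
  all_h1 <- list(haps$H1); all_h2 <- list(haps$H2)
  parents_used <- integer(0)
  sel_trait <- traits[1L]

  for (g in seq_len(cfg$n_gens)) {
    set.seed(substream_seed(cfg$seed, paste0("select-G", g)))
    cand <- data.frame(id = gen_ids,
                       sex = ped$sex[match(gen_ids, ped$id)])
    crit <- switch(cfg$selection_mode,
      random = NULL,
      phenotype = {
        ph <- phe_list[[g]]
        v <- ph$value[ph$trait == sel_trait]
        names(v) <- as.character(ph$id[ph$trait == sel_trait])
        v[as.character(gen_ids)]
      },
      ebv = {
        v <- current_ebv_criterion(ped, phe_list, sel_trait, h2[[sel_trait]],
                                   cfg)
        v[as.character(gen_ids)]
      })
    sel <- select_parents(cand, cfg$n_males_selected, cfg$n_females_selected,
                          criterion = crit,
                          mode = if (cfg$selection_mode == "random")
                            "random" else "criterion")
    parents_used <- union(parents_used, c(sel$sires, sel$dams))

    set.seed(substream_seed(cfg$seed, paste0("breed-G", g)))
    gen_haps$ids <- gen_ids
    off <- breed_generation(sel$sires, sel$dams, gen_haps, cfg)
    n_off <- nrow(off$haps$H1)
    new_ids <- max(ped$id) + seq_len(n_off)
    new_ped <- data.frame(id = new_ids,
                          sire = off$pedigree$sire, dam = off$pedigree$dam,
                          generation = g,
                          sex = ifelse(runif(n_off) < 0.5, "F", "M"),
                          hatch = sample.int(cfg$n_hatches_per_gen, n_off,
                                             replace = TRUE),
                          stringsAsFactors = FALSE)
    if (!any(new_ped$sex == "M")) new_ped$sex[1L] <- "M"
    if (!any(new_ped$sex == "F")) new_ped$sex[2L %% n_off + 1L] <- "F"
    ped <- rbind(ped, new_ped)

    bv_g <- true_bv(off$haps, arch)
    rownames(bv_g) <- as.character(new_ids)
    bv_all <- rbind(bv_all, bv_g)
    set.seed(substream_seed(cfg$seed, paste0("phenotypes-G", g)))
    phe_g <- simulate_phenotypes(bv_g,
                                 sprintf("G%d_H%d", g, new_ped$hatch),
                                 hatch_eff, h2)
    phe_g$id <- new_ids[phe_g$animal]
    phe_g$generation <- g
    phe_list[[g + 1L]] <- phe_g

    all_h1[[g + 1L]] <- off$haps$H1
    all_h2[[g + 1L]] <- off$haps$H2
    gen_haps <- off$haps
    gen_ids <- new_ids
  }

  phe <- do.call(rbind, phe_list)
  phe <- phe[, c("id", "trait", "value", "hatch_class", "generation")]
  if (!cfg$phenotype_both_sexes) {
    females <- ped$id[ped$sex == "F"]
    phe <- phe[phe$id %in% females, , drop = FALSE]
  }
  rownames(phe) <- NULL

  H1 <- do.call(rbind, all_h1)
  H2 <- do.call(rbind, all_h2)
  geno_all <- H1 + H2

  # genotyped set: all parents used for breeding + a fraction of the females
  # of each recorded generation
  set.seed(substream_seed(cfg$seed, "genotyping"))
  genotyped <- parents_used
  for (g in seq_len(cfg$n_gens)) {
    fem <- ped$id[ped$generation == g & ped$sex == "F"]
    keep <- fem[runif(length(fem)) < cfg$genotyped_fraction |
                  fem %in% parents_used]
    genotyped <- union(genotyped, keep)
  }
  genotyped <- sort(genotyped)
  geno <- geno_all[match(genotyped, ped$id), arch$panel, drop = FALSE]
  storage.mode(geno) <- "integer"

  # error injection (random different code), then missingness
  if (cfg$genotype_error_rate > 0) {
    flip <- which(runif(length(geno)) < cfg$genotype_error_rate)
    if (length(flip)) {
      old <- geno[flip]
      geno[flip] <- vapply(old, function(z)
        sample(setdiff(0:2, z), 1L), integer(1))
    }
  }
  if (cfg$missing_rate > 0)
    geno[runif(length(geno)) < cfg$missing_rate] <- NA_integer_

  snp_ids <- sprintf("snp%05d", arch$panel)
  map <- haps$map[arch$panel, ]
  genotypes <- gw_genotypes(geno, ids = genotyped,
                            map = data.frame(snp_id = snp_ids,
                                             chrom = map$chrom,
                                             pos = map$pos))

  ped_out <- data.frame(id = ped$id, sire = ped$sire, dam = ped$dam,
                        generation = ped$generation, sex = ped$sex,
                        hatch_class = sprintf("G%d_H%d", ped$generation,
                                              ped$hatch),
                        stringsAsFactors = FALSE)
  qtl_out <- data.frame(qtl_id = sprintf("qtl%05d", arch$qtl),
                        chrom = haps$map$chrom[arch$qtl],
                        pos = haps$map$pos[arch$qtl])
  qtl_out <- cbind(qtl_out, as.data.frame(arch$effects))

  structure(list(pedigree = ped_out, phenotypes = phe, genotypes = genotypes,
                 true_bv = bv_all, qtl = qtl_out, hatch_effects = hatch_eff,
                 cfg = cfg),
            class = "gw_population")
}

#' @export
print.gw_population <- function(x, ...) {
  cat(sprintf("<gw_population> %d animals over generations %d..%d\n",
              nrow(x$pedigree), min(x$pedigree$generation),
              max(x$pedigree$generation)))
  cat(sprintf("  %d genotyped (%d SNPs), %d phenotype records on %d trait(s)\n",
              nrow(x$genotypes$geno), ncol(x$genotypes$geno),
              nrow(x$phenotypes), length(unique(x$phenotypes$trait))))
  invisible(x)
}

# PBLUP EBV of current candidates used as the selection criterion in
# selection_mode = "ebv"; lambda fixed at the design value (1-h2)/h2.
current_ebv_criterion <- function(ped, phe_list, trait, h2, cfg) {
  phe <- do.call(rbind, phe_list)
  phe <- phe[phe$trait == trait, , drop = FALSE]
  if (!cfg$phenotype_both_sexes) {
    females <- ped$id[ped$sex == "F"]
    phe <- phe[phe$id %in% females, , drop = FALSE]
  }
  ped_df <- data.frame(id = ped$id, sire = ped$sire, dam = ped$dam,
                       generation = ped$generation)
  ainv <- build_a_inverse(ped_df)
  lambda <- max(1e-6, (1 - h2) / h2)
  vc <- list(sigma2_a = h2, sigma2_e = 1 - h2, lambda = lambda, h2 = h2)
  sys <- assemble_mme(data.frame(id = phe$id, value = phe$value,
                                 hatch_class = phe$hatch_class),
                      ainv, vc)
  sol <- solve_mme(sys)
  ebv <- sol$ebv$ebv
  names(ebv) <- as.character(sol$ebv$id)
  ebv
}
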