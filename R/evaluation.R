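# Generation-windowed training/validation design, the accuracy statistic,
# the sweep over numbers of training generations, and training-set
# size/composition scenarios.

# Caps on the number of training generations, matching the depth of data a
# windowed design can draw on for each model family.
K_MAX_PEDIGREE <- 10L
K_MAX_MARKER <- 8L

#' Build a generation-windowed training/validation design
#'
#' Training animals come from the `k` consecutive generations immediately
#' preceding the validation generation; validation animals are the
#' genotyped, phenotyped females of the validation generation (their
#' phenotypes are masked downstream). Pedigree-based designs accept at most
#' 10 training generations and marker-based designs at most 8.
#'
#' @param pop A `gw_population`.
#' @param validation_gen Index of the validation generation.
#' @param k Number of training generations.
#' @param method `"pblup_full"`, `"pblup_trunc"` or `"bayesb"`.
#' @param genotypes Genotypes used to define "genotyped" (e.g. the QC-
#'   filtered set); defaults to `pop$genotypes`.
#' @return List of class `gw_design`: `validation_gen`, `k`, `train_gens`,
#'   `method`, `train_ids`, `val_ids`.
#' @export
make_training_sets <- function(pop, validation_gen, k,
                               method = c("bayesb", "pblup_full",
                                          "pblup_trunc"),
                               genotypes = NULL) {
  method <- match.arg(method)
  if (k < 1L) stop_genwin("make_training_sets: k must be >= 1")
  cap <- if (method == "bayesb") K_MAX_MARKER else K_MAX_PEDIGREE
  if (k > cap)
    stop_genwin("make_training_sets: k = ", k, " exceeds the cap of ", cap,
                " training generations for ", method)
  genotypes <- genotypes %||% pop$genotypes
  ped <- pop$pedigree
  gens_avail <- sort(unique(ped$generation))
  train_gens <- (validation_gen - k):(validation_gen - 1L)
  if (!validation_gen %in% gens_avail)
    stop_genwin("validation generation ", validation_gen, " not in data")
  if (!all(train_gens %in% gens_avail))
    stop_genwin("k = ", k, " exceeds the generations available before G",
                validation_gen)
  genotyped <- rownames(genotypes$geno)
  phenotyped <- unique(as.character(pop$phenotypes$id))
  females <- as.character(ped$id[ped$sex == "F"])

  vg <- as.character(ped$id[ped$generation == validation_gen])
  val_ids <- intersect(intersect(vg, females),
                       intersect(genotyped, phenotyped))
  tr <- as.character(ped$id[ped$generation %in% train_gens])
  train_ids <- intersect(tr, phenotyped)
  if (method == "bayesb") train_ids <- intersect(train_ids, genotyped)
  if (length(val_ids) < 2L)
    stop_genwin("fewer than 2 validation animals in G", validation_gen)
  if (length(train_ids) < 2L)
    stop_genwin("fewer than 2 training animals for k = ", k)
  structure(list(validation_gen = validation_gen, k = k,
                 train_gens = train_gens, method = method,
                 train_ids = train_ids, val_ids = val_ids),
            class = "gw_design")
}

#' Adjust phenotypes for estimated fixed effects
#'
#' Subtracts the estimated hatch-within-generation class effect from each
#' record.
#'
#' @param phenotypes Data frame `id`, `value`, `hatch_class`.
#' @param fixed_effects Named vector of class-effect estimates; classes
#'   without an estimate are adjusted by the overall mean of the estimates.
#' @return The data frame with an added column `value_adj`.
#' @export
adjust_phenotypes <- function(phenotypes, fixed_effects) {
  eff <- fixed_effects[as.character(phenotypes$hatch_class)]
  eff[is.na(eff)] <- mean(fixed_effects)
  phenotypes$value_adj <- phenotypes$value - eff
  phenotypes
}

#' Prediction accuracy of (G)EBV in a validation set
#'
#' The Pearson correlation between the predicted breeding values and the
#' phenotypes adjusted for fixed effects, divided by the square root of the
#' (pedigree-based) trait heritability.
#'
#' @param ebv_table Data frame with `id` and an EBV column (`ebv` or
#'   `gebv`).
#' @param phenotypes Validation phenotypes (`id`, `value`, `hatch_class`).
#' @param fixed_effects Named vector of hatch-class effect estimates.
#' @param h2 Trait heritability used as the standardizer, in `(0, 1]`.
#' @return List of class `gw_accuracy`: `accuracy`, `n`.
#' @export
prediction_accuracy <- function(ebv_table, phenotypes, fixed_effects, h2) {
  if (h2 <= 0 || h2 > 1) stop_genwin("h2 must be in (0, 1]")
  col <- intersect(c("ebv", "gebv"), names(ebv_table))[1L]
  if (is.na(col)) stop_genwin("ebv_table needs an 'ebv' or 'gebv' column")
  phenotypes <- adjust_phenotypes(phenotypes, fixed_effects)
  m <- merge(data.frame(id = as.character(ebv_table$id),
                        pred = ebv_table[[col]]),
             data.frame(id = as.character(phenotypes$id),
                        obs = phenotypes$value_adj),
             by = "id")
  if (nrow(m) < 2L)
    stop_genwin("prediction_accuracy: fewer than 2 animals with EBV and phenotype")
  if (sd(m$pred) == 0 || sd(m$obs) == 0)
    stop_genwin("undefined correlation: zero variance in EBV or phenotypes")
  structure(list(accuracy = cor(m$pred, m$obs) / sqrt(h2), n = nrow(m)),
            class = "gw_accuracy")
}

# Fixed-effect estimates and variance components for one trait from a
# PBLUP fit on all phenotyped animals (validation generation included, so
# the hatch adjustment is available for every validation class).
trait_baseline <- function(pop, trait, ainv = NULL, vc = NULL) {
  phe <- pop$phenotypes[pop$phenotypes$trait == trait, , drop = FALSE]
  dat <- data.frame(id = phe$id, value = phe$value,
                    hatch_class = phe$hatch_class)
  ainv <- ainv %||% build_a_inverse(pop$pedigree)
  vc <- vc %||% estimate_variance_components(dat, ainv)
  sys <- assemble_mme(dat, ainv, vc)
  sol <- solve_mme(sys)
  list(vc = vc, beta = sol$beta, data = dat, ainv = ainv)
}

# One (trait, method, validation_gen, k) fit, returning the accuracy row.
fit_design <- function(pop, design, base, geno_qc, chain_length, burn_in,
                       seed) {
  trait_data <- base$data
  train_data <- trait_data[as.character(trait_data$id) %in%
                             design$train_ids, , drop = FALSE]
  if (design$method %in% c("pblup_full", "pblup_trunc")) {
    fit <- fit_pblup(pop$pedigree, train_data, base$vc,
                     masked_ids = design$val_ids,
                     truncate_depth = if (design$method == "pblup_trunc")
                       2L else NULL)
    ebv <- fit$ebv[fit$ebv$id %in% design$val_ids, , drop = FALSE]
  } else {
    train_geno <- subset_genotypes(geno_qc, ids = design$train_ids)
    priors <- derive_priors(base$vc, train_geno)
    post <- run_bayesb(train_geno, train_data, priors,
                       chain_length = chain_length, burn_in = burn_in,
                       seed = seed)
    val_geno <- subset_genotypes(geno_qc, ids = design$val_ids)
    ebv <- compute_gebv(val_geno, post)
  }
  val_phe <- trait_data[as.character(trait_data$id) %in% design$val_ids, ,
                        drop = FALSE]
  acc <- prediction_accuracy(ebv, val_phe, base$beta, base$vc$h2)
  data.frame(trait = NA_character_, method = design$method,
             validation_gen = design$validation_gen, k = design$k,
             accuracy = acc$accuracy, n_val = acc$n, seed = seed,
             stringsAsFactors = FALSE)
}

#' Sweep prediction accuracy over numbers of training generations
#'
#' For every combination of trait, method, validation generation and
#' window size `k`, fits the model on the `k` generations preceding the
#' validation generation and records the validation accuracy. Variance
#' components and the fixed-effect (hatch) estimates used for phenotype
#' adjustment are estimated once per trait from all phenotyped animals and
#' reused across the sweep, keeping the windowed fits comparable.
#'
#' @param pop A `gw_population`.
#' @param traits Trait names (default: all traits in the population).
#' @param methods Subset of `c("pblup_full", "pblup_trunc", "bayesb")`.
#' @param validation_gens Validation generation indices.
#' @param k_range Window sizes to evaluate.
#' @param chain_length,burn_in MCMC settings for the BayesB fits.
#' @param seed Master seed; each fit derives its own substream.
#' @param qc If `TRUE` (default), SNPs are QC-filtered before any
#'   marker-based fit.
#' @return Tidy data frame (`trait`, `method`, `validation_gen`, `k`,
#'   `accuracy`, `n_val`, `seed`). Infeasible or failed designs are
#'   recorded in the `"failures"` attribute rather than aborting the sweep.
#' @export
run_generation_sweep <- function(pop, traits = NULL,
                                 methods = c("pblup_full", "pblup_trunc",
                                             "bayesb"),
                                 validation_gens, k_range,
                                 chain_length = 10000, burn_in = 2000,
                                 seed = 1L, qc = TRUE) {
  traits <- traits %||% unique(pop$phenotypes$trait)
  methods <- match.arg(methods, several.ok = TRUE)
  geno_qc <- if (qc && "bayesb" %in% methods)
    qc_filter_snps(pop$genotypes, pop$pedigree)$genotypes
  else pop$genotypes
  ainv_full <- build_a_inverse(pop$pedigree)
  rows <- list(); fails <- list()
  for (trait in traits) {
    base <- trait_baseline(pop, trait, ainv = ainv_full)
    for (vg in validation_gens) for (k in k_range) for (m in methods) {
      tag <- paste(trait, m, vg, k, sep = "/")
      fit_seed <- substream_seed(seed, tag)
      row <- tryCatch({
        design <- make_training_sets(pop, vg, k, method = m,
                                     genotypes = geno_qc)
        r <- fit_design(pop, design, base, geno_qc, chain_length, burn_in,
                        fit_seed)
        r$trait <- trait
        r
      }, error = function(e) {
        fails[[tag]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(row)) rows[[tag]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- fails
  out
}

#' Training-set size and composition scenarios
#'
#' Re-creates the scenario design in which a fixed validation generation is
#' predicted from training sets that differ in total size and in how the
#' sampled animals are spread over generations: per scenario and replicate,
#' the stated number of animals is sampled without replacement from each
#' named generation (validation animals are fixed across replicates), a
#' BayesB model is fitted, and accuracy is recorded; the scenario summary
#' is the mean and SD over replicates.
#'
#' @param pop A `gw_population`.
#' @param trait Trait name.
#' @param scenarios List of named numeric vectors; names are generation
#'   indices and values the number of animals sampled from each, e.g.
#'   `list(s1 = c("9" = 250), s5 = c("8" = 125, "9" = 125))`.
#' @param validation_gen Fixed validation generation.
#' @param n_replicates Replicates per scenario (default 5).
#' @param chain_length,burn_in,seed MCMC settings and master seed.
#' @param qc QC-filter SNPs first (default `TRUE`).
#' @return Data frame (`scenario`, `n_gens`, `n_train`, `mean_accuracy`,
#'   `sd_accuracy`, `n_replicates`).
#' @export
run_size_composition_scenarios <- function(pop, trait, scenarios,
                                           validation_gen,
                                           n_replicates = 5,
                                           chain_length = 10000,
                                           burn_in = 2000, seed = 1L,
                                           qc = TRUE) {
  geno_qc <- if (qc) qc_filter_snps(pop$genotypes, pop$pedigree)$genotypes
  else pop$genotypes
  base <- trait_baseline(pop, trait)
  ped <- pop$pedigree
  genotyped <- rownames(geno_qc$geno)
  phenotyped <- unique(as.character(pop$phenotypes$id))
  eligible <- function(g)
    intersect(as.character(ped$id[ped$generation == g]),
              intersect(genotyped, phenotyped))
  design0 <- make_training_sets(pop, validation_gen, 1L, method = "bayesb",
                                genotypes = geno_qc)
  val_ids <- design0$val_ids
  val_phe <- base$data[as.character(base$data$id) %in% val_ids, ,
                       drop = FALSE]
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))

  out <- vector("list", length(scenarios))
  for (s in seq_along(scenarios)) {
    spec <- scenarios[[s]]
    gens <- as.integer(names(spec))
    accs <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      rs <- substream_seed(seed, paste(names(scenarios)[s], r, sep = "/"))
      set.seed(rs)
      ids <- character(0)
      for (gi in seq_along(gens)) {
        pool <- setdiff(eligible(gens[gi]), val_ids)
        if (length(pool) < spec[gi])
          stop_genwin("scenario ", names(scenarios)[s], ": generation G",
                      gens[gi], " has only ", length(pool),
                      " eligible animals (needs ", spec[gi], ")")
        ids <- c(ids, sample(pool, spec[gi]))
      }
      train_geno <- subset_genotypes(geno_qc, ids = ids)
      train_data <- base$data[as.character(base$data$id) %in% ids, ,
                              drop = FALSE]
      priors <- derive_priors(base$vc, train_geno)
      post <- run_bayesb(train_geno, train_data, priors,
                         chain_length = chain_length, burn_in = burn_in,
                         seed = rs)
      ebv <- compute_gebv(subset_genotypes(geno_qc, ids = val_ids), post)
      accs[r] <- prediction_accuracy(ebv, val_phe, base$beta,
                                     base$vc$h2)$accuracy
    }
    out[[s]] <- data.frame(scenario = names(scenarios)[s],
                           n_gens = length(gens),
                           n_train = sum(spec),
                           mean_accuracy = mean(accs),
                           sd_accuracy = sd(accs),
                           n_replicates = n_replicates,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
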