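# End-to-end orchestration: simulate -> QC -> variance components ->
# generation sweep -> scenarios -> optimum, with a reproducibility manifest.

study_config_keys <- c("sim", "validation_gens", "k_range", "methods",
                       "chain_length", "burn_in", "scenarios",
                       "scenario_trait", "scenario_validation_gen",
                       "k_max", "n_scenario_replicates")

#' Default configuration of the full study
#'
#' @param ... Overrides for any of: `sim` (list passed to [sim_config()]),
#'   `validation_gens`, `k_range`, `methods`, `chain_length`, `burn_in`,
#'   `scenarios`, `scenario_trait`, `scenario_validation_gen`,
#'   `n_scenario_replicates`, `k_max`.
#' @return A validated configuration list.
#' @export
study_config <- function(...) {
  cfg <- list(sim = list(),
              validation_gens = 7:9,
              k_range = 1:6,
              methods = c("pblup_full", "pblup_trunc", "bayesb"),
              chain_length = 10000, burn_in = 2000,
              scenarios = NULL, scenario_trait = NULL,
              scenario_validation_gen = NULL,
              n_scenario_replicates = 5,
              k_max = 8)
  extra <- list(...)
  unknown <- setdiff(names(extra), study_config_keys)
  if (length(unknown))
    stop_genwin("unknown configuration key(s): ",
                paste(unknown, collapse = ", "))
  modifyList(cfg, extra)
}

#' Read a study configuration from a YAML or JSON file
#'
#' The file mirrors the [study_config()] fields (`sim` as a nested map of
#' [sim_config()] arguments, `scenarios` as a map of generation-count
#' maps). Unknown keys are rejected before any computation.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated configuration list.
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_genwin("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$sim)) raw$sim <- as.list(raw$sim)
  if (!is.null(raw$scenarios))
    raw$scenarios <- lapply(raw$scenarios, unlist)
  do.call(study_config, raw)
}

#' Run the full study pipeline
#'
#' Executes every stage on a freshly simulated population: simulation, SNP
#' QC, per-trait REML variance components and marker heritability
#' (BayesC0), the accuracy sweep over training-generation windows for all
#' requested methods, optional size/composition scenarios, the per-trait
#' quadratic optima, and the correlation of optima with heritability.
#' Writes tidy CSVs plus a JSON manifest (config, seeds, timings, file
#' checksums) to `out_dir`. A stage failure is recorded in the manifest and
#' downstream stages are skipped.
#'
#' @param config A [study_config()] list.
#' @param out_dir Output directory.
#' @param seed Master seed (overrides `config$sim$seed`).
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_full_study <- function(config = study_config(), out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("genwin")),
                   master_seed = seed, config = config, stages = list())
  results <- list()
  failed <- FALSE

  stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(out, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(out),
                                       seconds = round(dt, 2))
      failed <<- TRUE
      return(NULL)
    }
    manifest$stages[[name]] <<- list(status = "ok", seconds = round(dt, 2))
    out
  }

  results$population <- stage("simulate", function() {
    sim_args <- modifyList(config$sim, list(seed = seed))
    pop <- simulate_population(do.call(sim_config, sim_args))
    write_population(pop, out_dir)
    pop
  })

  results$qc <- stage("qc", function() {
    qc <- qc_filter_snps(results$population$genotypes,
                         results$population$pedigree)
    write.csv(data.frame(filter = names(qc$removed),
                         removed = as.integer(qc$removed)),
              file.path(out_dir, "qc_report.csv"), row.names = FALSE)
    qc
  })

  results$h2 <- stage("heritability", function() {
    pop <- results$population
    ainv <- build_a_inverse(pop$pedigree)
    traits <- unique(pop$phenotypes$trait)
    rows <- lapply(traits, function(tr) {
      phe <- pop$phenotypes[pop$phenotypes$trait == tr, ]
      dat <- data.frame(id = phe$id, value = phe$value,
                        hatch_class = phe$hatch_class)
      vc <- estimate_variance_components(dat, ainv)
      geno <- results$qc$genotypes
      train <- intersect(rownames(geno$geno), as.character(dat$id))
      priors <- derive_priors(vc, geno, pi = 0)
      post <- run_bayesc0(subset_genotypes(geno, ids = train),
                          dat[as.character(dat$id) %in% train, ],
                          priors, chain_length = config$chain_length,
                          burn_in = config$burn_in,
                          seed = substream_seed(seed, paste0("h2q-", tr)))
      data.frame(trait = tr, h2_pedigree = vc$h2, se_h2 = vc$se_h2,
                 sigma2_a = vc$sigma2_a, sigma2_e = vc$sigma2_e,
                 h2_marker = post$h2_q, h2_marker_sd = post$h2_q_sd)
    })
    h2 <- do.call(rbind, rows)
    write.csv(h2, file.path(out_dir, "h2.csv"), row.names = FALSE)
    h2
  })

  results$sweep <- stage("sweep", function() {
    sw <- run_generation_sweep(results$population,
                               methods = config$methods,
                               validation_gens = config$validation_gens,
                               k_range = config$k_range,
                               chain_length = config$chain_length,
                               burn_in = config$burn_in,
                               seed = substream_seed(seed, "sweep"))
    write.csv(sw, file.path(out_dir, "accuracies.csv"), row.names = FALSE)
    sw
  })

  if (!is.null(config$scenarios)) {
    results$scenarios <- stage("scenarios", function() {
      sc <- run_size_composition_scenarios(
        results$population,
        trait = config$scenario_trait %||%
          unique(results$population$phenotypes$trait)[1L],
        scenarios = config$scenarios,
        validation_gen = config$scenario_validation_gen %||%
          max(config$validation_gens),
        n_replicates = config$n_scenario_replicates,
        chain_length = config$chain_length, burn_in = config$burn_in,
        seed = substream_seed(seed, "scenarios"))
      write.csv(sc, file.path(out_dir, "scenarios.csv"), row.names = FALSE)
      sc
    })
  }

  results$optima <- stage("optimum", function() {
    methods_opt <- intersect(config$methods, c("bayesb", "pblup_full"))
    tabs <- lapply(methods_opt, function(m) {
      tab <- optima_by_trait(results$sweep, method = m,
                             k_max = config$k_max)
      tab$method <- m
      tab
    })
    opt <- do.call(rbind, tabs)
    write.csv(opt, file.path(out_dir, "optima.csv"), row.names = FALSE)
    opt
  })

  results$correlations <- stage("correlations", function() {
    h2 <- results$h2
    opt <- results$optima[results$optima$method ==
                            intersect(c("bayesb", "pblup_full"),
                                      config$methods)[1L], ]
    ko <- setNames(opt$k_star, opt$trait)
    corr <- function(hh) tryCatch(correlate_optima_with_h2(ko,
                                    setNames(hh, h2$trait)),
                                  error = function(e) NA_real_)
    out <- data.frame(h2_type = c("pedigree", "marker"),
                      correlation = c(corr(h2$h2_pedigree),
                                      corr(h2$h2_marker)))
    write.csv(out, file.path(out_dir, "correlations.csv"),
              row.names = FALSE)
    out
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(results)
}

#' Generate a small canned dataset for tests and examples
#'
#' A deterministic, sub-200-animal, sub-200-SNP population with known true
#' breeding values and at least one guaranteed Mendelian inconsistency (one
#' offspring genotype of a fully genotyped trio is forced to an impossible
#' code so QC filters are exercisable).
#'
#' @param seed Master seed.
#' @param dir Optional directory; when given, the population is also
#'   written out with [write_population()].
#' @return The `gw_population` (invisibly when `dir` is given).
#' @export
generate_fixtures <- function(seed = 20260101L, dir = NULL) {
  cfg <- sim_config(n_founders = 30, n_burnin_gens = 30, n_gens = 4,
                    n_offspring_per_gen = 40, n_males_selected = 5,
                    n_females_selected = 10, n_chrom = 3,
                    chrom_length_morgans = 1, n_snps = 150, n_qtl = 30,
                    target_h2 = c(fix50 = 0.5), n_hatches_per_gen = 2,
                    selection_mode = "phenotype", missing_rate = 0.02,
                    genotype_error_rate = 0.01, seed = seed)
  pop <- simulate_population(cfg)
  # force one detectable Mendelian inconsistency in a complete trio
  g <- pop$genotypes$geno
  ped <- pop$pedigree
  ids <- rownames(g)
  trio <- ped[as.character(ped$id) %in% ids &
                as.character(ped$sire) %in% ids &
                as.character(ped$dam) %in% ids, ][1L, ]
  if (nrow(trio) == 1L && !is.na(trio$id)) {
    s <- g[as.character(trio$sire), ]
    d <- g[as.character(trio$dam), ]
    j <- which(!is.na(s) & !is.na(d) & s == 0L & d == 0L)[1L]
    if (!is.na(j)) g[as.character(trio$id), j] <- 2L
  }
  pop$genotypes <- gw_genotypes(g, map = pop$genotypes$map)
  if (!is.null(dir)) {
    write_population(pop, dir)
    return(invisible(pop))
  }
  pop
}
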