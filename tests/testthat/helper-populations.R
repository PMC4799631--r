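# Small simulated populations shared by several test files; memoised so
# each is generated once per test run.

.pop_cache <- new.env(parent = emptyenv())

small_cfg <- function(seed = 101, ...) {
  args <- modifyList(list(n_founders = 40, n_burnin_gens = 30, n_gens = 4,
                          n_offspring_per_gen = 100, n_males_selected = 10,
                          n_females_selected = 20, n_chrom = 3,
                          n_snps = 200, n_qtl = 40,
                          target_h2 = c(tt = 0.5), n_hatches_per_gen = 2,
                          missing_rate = 0.02,
                          genotype_error_rate = 0.005, seed = seed),
                     list(...))
  do.call(sim_config, args)
}

cached_pop <- function(key, cfg) {
  if (is.null(.pop_cache[[key]]))
    .pop_cache[[key]] <- simulate_population(cfg)
  .pop_cache[[key]]
}

small_pop <- function() cached_pop("small", small_cfg())

# single-trait phenotype frame for a population
trait_data <- function(pop, trait = NULL) {
  trait <- trait %||% unique(pop$phenotypes$trait)[1]
  phe <- pop$phenotypes[pop$phenotypes$trait == trait, ]
  data.frame(id = phe$id, value = phe$value, hatch_class = phe$hatch_class,
             generation = phe$generation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
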