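#' Configuration for the breeding-population simulator
#'
#' Collects and validates every knob of the synthetic population generator.
#' The defaults emulate the structure of a closed layer-chicken nucleus line
#' under genomic-era truncation selection: discrete non-overlapping
#' generations of 600 birds, 50 sires and 50 dams selected per generation,
#' roughly 300 genotyped, phenotyped females per generation, and a SNP panel
#' whose linkage disequilibrium with the QTL is built up by a long
#' random-mating burn-in of a small (Ne = `n_founders`) population.
#'
#' @param n_founders Number of founder animals (also the effective size of
#'   the burn-in population).
#' @param n_burnin_gens Generations of historical random mating used to
#'   generate LD before pedigree recording starts.
#' @param n_gens Number of recorded (pedigreed) generations bred after the
#'   founders.
#' @param n_offspring_per_gen Offspring born in each recorded generation.
#' @param n_males_selected,n_females_selected Parents of each sex kept by
#'   truncation selection each generation.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_morgans Genetic length of each chromosome (Morgans).
#' @param n_snps Size of the SNP panel (polymorphic markers retained after
#'   the burn-in).
#' @param n_qtl Number of additive QTL underlying every trait.
#' @param target_h2 Narrow-sense heritability of each simulated trait, as a
#'   (optionally named) numeric vector in `(0, 1]`; one trait per element.
#'   `h2 = 1` is permitted for noise-free limit checks.
#' @param n_hatches_per_gen Number of hatch (contemporary-group) classes per
#'   generation; hatch-within-generation is the fixed effect of the models.
#' @param hatch_effect_sd Standard deviation of hatch-class effects, in
#'   phenotypic standard-deviation units.
#' @param selection_mode `"random"`, `"phenotype"` (own record) or `"ebv"`
#'   (pedigree BLUP re-estimated each generation).
#' @param genotyped_fraction Fraction of females per recorded generation that
#'   are genotyped (all selected parents are genotyped regardless).
#' @param missing_rate Per-entry probability that a genotype call is missing.
#' @param genotype_error_rate Per-entry probability that a genotype is
#'   replaced by a random different code (creates Mendelian inconsistencies).
#' @param qtl_on_panel If `TRUE`, QTL are drawn from the SNP panel itself;
#'   by default they are off-panel, so markers tag QTL only through LD.
#' @param phenotype_both_sexes If `TRUE`, male phenotypes are recorded in
#'   the output as well (they are always simulated internally so that males
#'   can be ranked under phenotypic selection).
#' @param seed Master seed; every stage derives substreams from it via
#'   [substream_seed()].
#' @return An object of class `gw_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_gens = 3, n_offspring_per_gen = 60,
#'                   n_males_selected = 5, n_females_selected = 10,
#'                   n_snps = 100, n_qtl = 10, seed = 42)
sim_config <- function(n_founders = 100,
                       n_burnin_gens = 100,
                       n_gens = 9,
                       n_offspring_per_gen = 600,
                       n_males_selected = 50,
                       n_females_selected = 50,
                       n_chrom = 10,
                       chrom_length_morgans = 1,
                       n_snps = 1000,
                       n_qtl = 100,
                       target_h2 = c(t020 = 0.2, t050 = 0.5, t070 = 0.7),
                       n_hatches_per_gen = 3,
                       hatch_effect_sd = 0.25,
                       selection_mode = c("phenotype", "random", "ebv"),
                       genotyped_fraction = 1,
                       missing_rate = 0.02,
                       genotype_error_rate = 0.002,
                       qtl_on_panel = FALSE,
                       phenotype_both_sexes = FALSE,
                       seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  cfg <- list(n_founders = as.integer(n_founders),
              n_burnin_gens = as.integer(n_burnin_gens),
              n_gens = as.integer(n_gens),
              n_offspring_per_gen = as.integer(n_offspring_per_gen),
              n_males_selected = as.integer(n_males_selected),
              n_females_selected = as.integer(n_females_selected),
              n_chrom = as.integer(n_chrom),
              chrom_length_morgans = as.numeric(chrom_length_morgans),
              n_snps = as.integer(n_snps),
              n_qtl = as.integer(n_qtl),
              target_h2 = target_h2,
              n_hatches_per_gen = as.integer(n_hatches_per_gen),
              hatch_effect_sd = as.numeric(hatch_effect_sd),
              selection_mode = selection_mode,
              genotyped_fraction = as.numeric(genotyped_fraction),
              missing_rate = as.numeric(missing_rate),
              genotype_error_rate = as.numeric(genotype_error_rate),
              qtl_on_panel = isTRUE(qtl_on_panel),
              phenotype_both_sexes = isTRUE(phenotype_both_sexes),
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_chrom < 1L || n_snps < 1L)
      stop_genwin("configuration error: need at least one chromosome and one SNP")
    if (n_founders < 2L)
      stop_genwin("configuration error: need at least two founders")
    if (chrom_length_morgans < 0)
      stop_genwin("configuration error: chromosome length must be >= 0 Morgans")
    if (any(target_h2 <= 0) || any(target_h2 > 1))
      stop_genwin("configuration error: target_h2 must lie in (0, 1]")
    if (n_qtl < 0L || (n_qtl == 0L && any(target_h2 > 0)))
      stop_genwin("configuration error: n_qtl = 0 is incompatible with target_h2 > 0")
    if (qtl_on_panel && n_qtl > n_snps)
      stop_genwin("configuration error: n_qtl exceeds panel size with qtl_on_panel = TRUE")
    if (n_males_selected + n_females_selected < 2L)
      stop_genwin("configuration error: must select at least one parent of each sex")
    if (n_males_selected > n_offspring_per_gen ||
        n_females_selected > n_offspring_per_gen)
      stop_genwin("configuration error: selected counts exceed offspring per generation")
    if (genotyped_fraction <= 0 || genotyped_fraction > 1)
      stop_genwin("configuration error: genotyped_fraction must be in (0, 1]")
    if (missing_rate < 0 || missing_rate >= 1)
      stop_genwin("configuration error: missing_rate must be in [0, 1)")
    if (genotype_error_rate < 0 || genotype_error_rate >= 1)
      stop_genwin("configuration error: genotype_error_rate must be in [0, 1)")
    if (n_hatches_per_gen < 1L)
      stop_genwin("configuration error: need at least one hatch per generation")
  })
  if (is.null(names(cfg$target_h2)))
    names(cfg$target_h2) <- paste0("trait", seq_along(cfg$target_h2))
  structure(cfg, class = "gw_sim_config")
}

#' @export
print.gw_sim_config <- function(x, ...) {
  cat("<gw_sim_config>\n")
  cat(sprintf("  %d founders, %d burn-in + %d recorded generations, %d offspring/gen\n",
              x$n_founders, x$n_burnin_gens, x$n_gens, x$n_offspring_per_gen))
  cat(sprintf("  selection: %s (%dM/%dF)\n", x$selection_mode,
              x$n_males_selected, x$n_females_selected))
  cat(sprintf("  genome: %d chromosomes x %.2g M, %d SNPs, %d QTL (%s panel)\n",
              x$n_chrom, x$chrom_length_morgans, x$n_snps, x$n_qtl,
              if (x$qtl_on_panel) "on" else "off"))
  cat(sprintf("  traits: %s\n",
              paste(sprintf("%s(h2=%.2f)", names(x$target_h2), x$target_h2),
                    collapse = ", ")))
  invisible(x)
}
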