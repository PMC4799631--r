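# SNP quality control: call rate, minor allele frequency, and
# parent-offspring Mendelian-inconsistency filters, applied sequentially.

#' Filter SNPs on call rate, MAF and Mendelian inconsistency
#'
#' Filters are applied in order, each on the survivors of the previous one:
#' (1) SNPs with a call rate *lower than* `call_rate` are removed (a SNP at
#' exactly the threshold is kept); (2) SNPs with a minor allele frequency
#' *lower than* `maf` are removed; (3) SNPs whose parent-offspring
#' Mendelian-inconsistency rate is *higher than* `mendel_rate` are removed.
#' The inconsistency rate of a SNP is the number of inconsistent informative
#' trios divided by the number of informative trios, where a trio (both
#' parents and the offspring genotyped) is informative when an inconsistent
#' offspring code is detectable (i.e. the parents are not both
#' heterozygous) and inconsistent when the offspring dosage is impossible
#' under Mendelian transmission.
#'
#' @param genotypes A `gw_genotypes` object.
#' @param ped Pedigree data frame (`id`, `sire`, `dam`); used to form trios
#'   among genotyped animals. `NULL` skips the Mendelian filter.
#' @param call_rate,maf,mendel_rate Thresholds (defaults 0.95, 0.025, 0.05).
#' @return List of class `gw_qc`: filtered `genotypes`, `removed` (named
#'   counts per filter), `n_kept`, and `mendel_rates` (per surviving SNP
#'   before the last filter).
#' @export
qc_filter_snps <- function(genotypes, ped = NULL,
                           call_rate = 0.95, maf = 0.025,
                           mendel_rate = 0.05) {
  stopifnot(inherits(genotypes, "gw_genotypes"))
  g <- genotypes$geno
  removed <- c(call_rate = 0L, maf = 0L, mendelian = 0L)

  cr <- colMeans(!is.na(g))
  drop1 <- cr < call_rate
  removed["call_rate"] <- sum(drop1)
  g <- g[, !drop1, drop = FALSE]

  p <- colMeans(g, na.rm = TRUE) / 2
  m <- pmin(p, 1 - p)
  drop2 <- m < maf
  removed["maf"] <- sum(drop2)
  g <- g[, !drop2, drop = FALSE]

  rates <- setNames(rep(0, ncol(g)), colnames(g))
  if (!is.null(ped) && ncol(g) > 0L) {
    rates <- setNames(mendelian_rates(g, ped), colnames(g))
    drop3 <- rates > mendel_rate
    removed["mendelian"] <- sum(drop3)
    g <- g[, !drop3, drop = FALSE]
  }
  if (ncol(g) == 0L)
    stop_genwin("qc_filter_snps: no SNPs survive the filters")
  keep_ids <- colnames(g)
  map <- genotypes$map[match(keep_ids, genotypes$map$snp_id), , drop = FALSE]
  structure(list(genotypes = gw_genotypes(g, map = map),
                 removed = removed, n_kept = ncol(g),
                 mendel_rates = rates),
            class = "gw_qc")
}

# Per-SNP Mendelian-inconsistency rate over informative genotyped trios.
mendelian_rates <- function(g, ped) {
  ids <- rownames(g)
  trio <- ped[as.character(ped$id) %in% ids &
                as.character(ped$sire) %in% ids &
                as.character(ped$dam) %in% ids, , drop = FALSE]
  if (nrow(trio) == 0L) return(rep(0, ncol(g)))
  O <- g[as.character(trio$id), , drop = FALSE]
  S <- g[as.character(trio$sire), , drop = FALSE]
  D <- g[as.character(trio$dam), , drop = FALSE]
  lb <- (S == 2L) + (D == 2L)            # minimum transmissible dosage
  ub <- (S >= 1L) + (D >= 1L)            # maximum transmissible dosage
  complete <- !is.na(O) & !is.na(S) & !is.na(D)
  informative <- complete & !(S == 1L & D == 1L)
  inconsistent <- informative & (O < lb | O > ub)
  ninf <- colSums(informative, na.rm = TRUE)
  ninc <- colSums(inconsistent, na.rm = TRUE)
  ifelse(ninf > 0, ninc / ninf, 0)
}

#' @export
print.gw_qc <- function(x, ...) {
  cat(sprintf("<gw_qc> kept %d SNPs; removed: call rate %d, MAF %d, Mendelian %d\n",
              x$n_kept, x$removed["call_rate"], x$removed["maf"],
              x$removed["mendelian"]))
  invisible(x)
}
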