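# Genotype container: animals x SNPs dosage codes {0,1,2,NA} plus map and
# allele frequencies computed over non-missing entries.

#' Construct a genotype matrix object
#'
#' @param geno Integer matrix of dosage codes 0/1/2 with `NA` for missing
#'   calls (animals in rows, SNPs in columns).
#' @param ids Animal ids (row identity); defaults to existing rownames.
#' @param map Data frame with columns `snp_id`, `chrom`, `pos` (Morgans);
#'   defaults to a single pseudo-chromosome.
#' @return An object of class `gw_genotypes`: list with `geno` (rownames =
#'   ids, colnames = snp ids), `map`, and allele frequencies `p` (column
#'   means of non-missing codes divided by 2).
#' @export
gw_genotypes <- function(geno, ids = rownames(geno), map = NULL) {
  geno <- as.matrix(geno)
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad))
    stop_genwin("genotype codes must be 0, 1, 2 or NA")
  if (is.null(ids)) ids <- seq_len(nrow(geno))
  if (is.null(map)) {
    ids_snp <- colnames(geno) %||% sprintf("snp%05d", seq_len(ncol(geno)))
    map <- data.frame(snp_id = ids_snp, chrom = 1L,
                      pos = seq_len(ncol(geno)) * 0.01)
  }
  stopifnot(nrow(map) == ncol(geno))
  rownames(geno) <- as.character(ids)
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, map = map,
                 p = colMeans(geno, na.rm = TRUE) / 2),
            class = "gw_genotypes")
}

#' @export
print.gw_genotypes <- function(x, ...) {
  cat(sprintf("<gw_genotypes> %d animals x %d SNPs (%.2f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Subset a genotype object by animals and/or SNPs
#' @param x A `gw_genotypes` object.
#' @param ids Animal ids to keep (default all).
#' @param snps SNP ids or column indices to keep (default all).
#' @return A `gw_genotypes` with allele frequencies recomputed on the subset.
#' @export
subset_genotypes <- function(x, ids = NULL, snps = NULL) {
  stopifnot(inherits(x, "gw_genotypes"))
  g <- x$geno
  map <- x$map
  if (!is.null(snps)) {
    j <- if (is.character(snps)) match(snps, map$snp_id) else snps
    if (anyNA(j)) stop_genwin("unknown SNP ids in subset")
    g <- g[, j, drop = FALSE]; map <- map[j, , drop = FALSE]
  }
  if (!is.null(ids)) {
    i <- match(as.character(ids), rownames(g))
    if (anyNA(i)) stop_genwin("unknown animal ids in subset")
    g <- g[i, , drop = FALSE]
  }
  gw_genotypes(g, map = map)
}

#' Mean-impute missing genotype codes
#'
#' Missing dosage codes are replaced by twice the allele frequency `2 p_j`
#' computed from the non-missing entries (optionally frequencies supplied
#' from a reference/training set), giving a numeric matrix suitable for the
#' whole-genome regression samplers and for GEBV computation.
#'
#' @param x A `gw_genotypes` object.
#' @param p Optional named allele-frequency vector to impute with.
#' @return Numeric matrix (animals x SNPs), no missing values.
#' @export
impute_genotypes <- function(x, p = NULL) {
  stopifnot(inherits(x, "gw_genotypes"))
  g <- x$geno
  storage.mode(g) <- "double"
  p <- p %||% x$p
  miss <- which(is.na(g), arr.ind = TRUE)
  if (nrow(miss)) g[miss] <- 2 * p[colnames(g)[miss[, 2L]]]
  if (anyNA(g)) stop_genwin("imputation left missing values (all-missing SNP?)")
  g
}
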