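# Plain-text I/O: pedigree/phenotype CSV, genotype TSV, PLINK .ped/.map,
# and a matrix-market export of the sparse A-inverse.

#' Write a simulated population to plain-text files
#'
#' Writes `pedigree.csv` (id, sire, dam, generation, sex, hatch_class;
#' 0 = unknown parent), `phenotypes.csv` (id, trait, value, hatch_class,
#' generation), `genotypes.tsv` (rows = animals, columns = SNP ids, codes
#' 0/1/2, NA = missing), `map.csv`, and `true_bv.csv` (validation-only
#' truth).
#'
#' @param pop A `gw_population`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(pedigree = file.path(dir, "pedigree.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             map = file.path(dir, "map.csv"),
             true_bv = file.path(dir, "true_bv.csv"))
  write.csv(pop$pedigree, files["pedigree"], row.names = FALSE)
  write.csv(pop$phenotypes, files["phenotypes"], row.names = FALSE)
  write_genotypes_tsv(pop$genotypes, files["genotypes"])
  write.csv(pop$genotypes$map, files["map"], row.names = FALSE)
  bv <- data.frame(id = rownames(pop$true_bv), pop$true_bv,
                   check.names = FALSE)
  write.csv(bv, files["true_bv"], row.names = FALSE)
  invisible(files)
}

#' Write genotypes as a tab-separated table
#' @param genotypes A `gw_genotypes` object.
#' @param path Output file; first column `id`, then one column per SNP.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes$geno), genotypes$geno,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read genotypes from a tab-separated table
#' @param path File written by [write_genotypes_tsv()].
#' @param map Optional map data frame; default is a single pseudo-chromosome.
#' @return A `gw_genotypes` object.
#' @export
read_genotypes_tsv <- function(path, map = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  gw_genotypes(g, ids = df$id, map = map)
}

#' Read a pedigree CSV
#' @param path File with columns id, sire, dam, generation, sex, hatch_class.
#' @return Data frame with unknown parents coded 0.
#' @export
read_pedigree_csv <- function(path) {
  ped <- read.csv(path, stringsAsFactors = FALSE)
  ped$sire[is.na(ped$sire)] <- 0L
  ped$dam[is.na(ped$dam)] <- 0L
  ped
}

#' Read a long-format phenotype CSV
#' @param path File with columns id, trait, value, hatch_class, generation.
#' @return Data frame.
#' @export
read_phenotypes_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write genotypes in PLINK .ped/.map text format
#'
#' Dosage 0/1/2 is written as allele pairs `A A` / `A B` / `B B` (missing =
#' `0 0`); the .map file carries chromosome, SNP id, position in
#' centimorgans, and an integer base-pair stand-in derived from the genetic
#' position.
#'
#' @param genotypes A `gw_genotypes` object.
#' @param prefix Output prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @param ped Optional pedigree data frame supplying sire/dam/sex columns.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(genotypes, prefix, ped = NULL) {
  g <- genotypes$geno
  n <- nrow(g)
  ids <- rownames(g)
  a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, "B", "A"))
  a2 <- ifelse(is.na(g), "0", ifelse(g == 2, "B", "A"))
  all_cols <- matrix("", n, 2L * ncol(g))
  all_cols[, seq(1L, 2L * ncol(g), by = 2L)] <- a1
  all_cols[, seq(2L, 2L * ncol(g), by = 2L)] <- a2
  info <- data.frame(fid = "F0", iid = ids, pat = 0L, mat = 0L, sex = 0L,
                     phe = -9)
  if (!is.null(ped)) {
    m <- match(ids, as.character(ped$id))
    info$pat <- ifelse(is.na(m), 0L, ped$sire[m])
    info$mat <- ifelse(is.na(m), 0L, ped$dam[m])
    info$sex <- ifelse(is.na(m), 0L, ifelse(ped$sex[m] == "M", 1L, 2L))
  }
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  utils::write.table(cbind(info, all_cols), ped_path, sep = " ",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  map <- genotypes$map
  utils::write.table(data.frame(map$chrom, map$snp_id,
                                100 * map$pos,
                                as.integer(round(1e6 * map$pos)) + 1L),
                     map_path, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK .ped/.map text files into a genotype object
#' @param prefix Prefix used by [write_plink()].
#' @return A `gw_genotypes` object (allele B counted as the dosage allele).
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"),
                           col.names = c("chrom", "snp_id", "cm", "bp"))
  raw <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  ids <- raw[, 2L]
  al <- as.matrix(raw[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1L, ncol(al), by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, ncol(al), by = 2L), drop = FALSE]
  g <- (a1 == "B") + (a2 == "B")
  g[a1 == "0" | a2 == "0"] <- NA
  storage.mode(g) <- "integer"
  gw_genotypes(g, ids = ids,
               map = data.frame(snp_id = map$snp_id, chrom = map$chrom,
                                pos = map$cm / 100))
}

#' Export a sparse A-inverse in matrix-market coordinate format
#' @param a_inv A [build_a_inverse()] object.
#' @param path Output `.mtx` file.
#' @export
write_a_inverse_mm <- function(a_inv, path) {
  stopifnot(inherits(a_inv, "gw_ainverse"))
  Matrix::writeMM(methods::as(a_inv$ainv, "generalMatrix"), path)
  invisible(path)
}
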