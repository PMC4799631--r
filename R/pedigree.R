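# Pedigree algebra: numerator relationship matrix A (tabular method with
# inbreeding), its sparse inverse by Henderson's rules, inbreeding
# coefficients, and generation truncation.

# Normalise a pedigree data frame: columns id, sire, dam (+ optional
# generation); unknown parents coded 0 or NA (stored as 0). Returns the
# pedigree in topological order (parents before offspring) or errors,
# naming ids on a cycle.
sort_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  ped$sire[is.na(ped$sire)] <- 0L
  ped$dam[is.na(ped$dam)] <- 0L
  if (anyDuplicated(ped$id))
    stop_genwin("pedigree error: duplicated animal ids")
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  placed <- logical(n)
  order_out <- integer(n)
  k <- 0L
  repeat {
    ready <- !placed & (si == 0L | placed[pmax(si, 1L)]) &
                       (di == 0L | placed[pmax(di, 1L)])
    if (!any(ready)) break
    idx <- which(ready)
    order_out[k + seq_along(idx)] <- idx
    k <- k + length(idx)
    placed[idx] <- TRUE
  }
  if (k < n)
    stop_genwin("pedigree error: cycle involving ids ",
                paste(ped$id[!placed], collapse = ", "))
  ped[order_out, , drop = FALSE]
}

#' Build the numerator relationship matrix A
#'
#' Tabular (recursive) method with inbreeding: for animal `y` with parents
#' `s`, `d`, `a_xy = 0.5 (a_{x,s} + a_{x,d})` for older `x`, and
#' `a_yy = 1 + 0.5 a_{s,d}`; unknown parents contribute zero. Dense, so
#' intended for pedigrees up to a few thousand animals.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam` (0/NA = unknown).
#' @return List of class `gw_amatrix`: `ids` (in topological order), dense
#'   symmetric matrix `A`, and inbreeding coefficients `f` (`diag(A) - 1`).
#' @export
build_a_matrix <- function(ped) {
  ped <- sort_pedigree(as.data.frame(ped))
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[seq_len(i - 1L), s]
      if (d > 0L) row <- row + 0.5 * A[seq_len(i - 1L), d]
      A[seq_len(i - 1L), i] <- row
      A[i, seq_len(i - 1L)] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  ids <- as.character(ped$id)
  dimnames(A) <- list(ids, ids)
  structure(list(ids = ids, A = A, f = diag(A) - 1), class = "gw_amatrix")
}

#' Inbreeding coefficients from a pedigree
#'
#' `F_x = 0.5 a(sire, dam)`. Computed economically: the tabular A is built
#' only on the closure of animals that appear as parents (plus their
#' ancestors), which is small in breeding populations; terminal animals get
#' their F from the parental kinship block.
#'
#' @inheritParams build_a_matrix
#' @return Named numeric vector of inbreeding coefficients (names = ids).
#' @export
inbreeding <- function(ped) {
  input_ids <- as.character(as.data.frame(ped)$id)
  ped <- sort_pedigree(as.data.frame(ped))
  id <- ped$id
  is_parent <- id %in% c(ped$sire, ped$dam)
  # ancestor closure of the parent set
  keep <- is_parent
  repeat {
    par_needed <- id %in% c(ped$sire[keep], ped$dam[keep])
    new_keep <- keep | par_needed
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  f <- setNames(numeric(nrow(ped)), as.character(id))
  if (any(keep)) {
    sub <- ped[keep, , drop = FALSE]
    sub$sire[!(sub$sire %in% sub$id)] <- 0L
    sub$dam[!(sub$dam %in% sub$id)] <- 0L
    am <- build_a_matrix(sub)
    f[am$ids] <- am$f
    both <- ped$sire %in% sub$id & ped$dam %in% sub$id
    idx_s <- match(as.character(ped$sire), am$ids)
    idx_d <- match(as.character(ped$dam), am$ids)
    f[both & !keep] <- 0.5 * am$A[cbind(idx_s[both & !keep],
                                        idx_d[both & !keep])]
    # animals in the closure already have exact F from the diagonal
    f[as.character(sub$id)] <- am$f
  }
  f[input_ids]
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding. For animal `x` with parents `s`, `d`,
#' the Mendelian-sampling variance is `d_x = 0.5 - 0.25 (F_s + F_d)` (an
#' unknown parent enters with `F = -1`, reproducing the 0.75 and 1 cases);
#' with `alpha = 1/d_x` the contributions are `alpha` to `(x,x)`,
#' `-alpha/2` to each known parent-offspring cell, and `alpha/4` to each
#' known parent-pair cell (including parent diagonals).
#'
#' @inheritParams build_a_matrix
#' @return List of class `gw_ainverse`: `ids` (topological order), sparse
#'   symmetric `ainv` (`Matrix::dgCMatrix`), and inbreeding vector `f`.
#' @export
build_a_inverse <- function(ped) {
  ped <- sort_pedigree(as.data.frame(ped))
  n <- nrow(ped)
  f <- unname(inbreeding(ped)) # ped already sorted: f aligns with its rows
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  fs <- rep(-1, n); fs[si > 0L] <- f[si[si > 0L]]
  fd <- rep(-1, n); fd[di > 0L] <- f[di[di > 0L]]
  alpha <- 1 / (0.5 - 0.25 * (fs + fd))
  i_idx <- seq_len(n)

  ii <- c(i_idx)
  jj <- c(i_idx)
  xx <- c(alpha)
  ks <- which(si > 0L)
  ii <- c(ii, ks, si[ks], si[ks])
  jj <- c(jj, si[ks], ks, si[ks])
  xx <- c(xx, -alpha[ks] / 2, -alpha[ks] / 2, alpha[ks] / 4)
  kd <- which(di > 0L)
  ii <- c(ii, kd, di[kd], di[kd])
  jj <- c(jj, di[kd], kd, di[kd])
  xx <- c(xx, -alpha[kd] / 2, -alpha[kd] / 2, alpha[kd] / 4)
  kb <- which(si > 0L & di > 0L)
  ii <- c(ii, si[kb], di[kb])
  jj <- c(jj, di[kb], si[kb])
  xx <- c(xx, alpha[kb] / 4, alpha[kb] / 4)

  ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(as.character(ped$id),
                                               as.character(ped$id)))
  structure(list(ids = as.character(ped$id), ainv = ainv, f = f),
            class = "gw_ainverse")
}

#' Truncate a pedigree to a generation window around a focal set
#'
#' Keeps the focal animals (typically training + validation) and their
#' ancestors born within `depth` generations before the oldest focal
#' generation; parents falling outside the window are recoded as unknown.
#' Matches the practice of tracing relatives back a fixed number of
#' generations when building A for a windowed evaluation.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam`, `generation`.
#' @param focal_ids Ids of the focal animals.
#' @param depth Number of generations of ancestors to retain (default 2).
#' @return The truncated pedigree data frame (same columns), closed under
#'   the retained ancestor relation.
#' @export
truncate_pedigree <- function(ped, focal_ids, depth = 2L) {
  ped <- as.data.frame(ped)
  stopifnot("generation" %in% names(ped))
  if (length(focal_ids) == 0L)
    stop_genwin("truncate_pedigree: empty focal set")
  if (!all(focal_ids %in% ped$id))
    stop_genwin("truncate_pedigree: focal ids absent from pedigree")
  g_min <- min(ped$generation[ped$id %in% focal_ids]) - depth
  keep <- ped$id %in% focal_ids
  repeat {
    parents <- c(ped$sire[keep], ped$dam[keep])
    new_keep <- keep | (ped$id %in% parents & ped$generation >= g_min)
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  out <- ped[keep, , drop = FALSE]
  out$sire[!(out$sire %in% out$id)] <- 0L
  out$dam[!(out$dam %in% out$id)] <- 0L
  rownames(out) <- NULL
  out
}
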