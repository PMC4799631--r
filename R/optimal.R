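# Optimal number of training generations: quadratic regression of accuracy
# on window size, the capped vertex, and the correlation of per-trait
# optima with heritability.

#' Fit the quadratic accuracy-vs-generations regression for one trait
#'
#' Ordinary least squares for `y_k = a k^2 + b k + c + e`, pooling all
#' accuracy records of one trait and method over validation generations.
#' Two-sided t-tests are reported for `a` and `b`; the fit is flagged
#' quadratic-significant when the p-value of `a` is below `p_threshold`.
#'
#' @param records Data frame with columns `k` and `accuracy` (all records
#'   for one trait/method).
#' @param p_threshold Significance threshold for the flag (default 0.01).
#' @return List of class `gw_quadfit`: `a`, `b`, `c`, `p_a`, `p_b`,
#'   `significant`, `residuals`, `n`.
#' @export
fit_quadratic <- function(records, p_threshold = 0.01) {
  records <- records[is.finite(records$accuracy), , drop = FALSE]
  if (nrow(records) < 4L || length(unique(records$k)) < 3L)
    stop_genwin("fit_quadratic: need >= 4 records spanning >= 3 distinct k")
  fit <- lm(accuracy ~ I(k^2) + k, data = records)
  # noiseless inputs give an exact fit; the p-values are then 0 by
  # convention and summary()'s perfect-fit warning is expected
  sm <- suppressWarnings(summary(fit)$coefficients)
  a <- unname(coef(fit)["I(k^2)"])
  b <- unname(coef(fit)["k"])
  cc <- unname(coef(fit)["(Intercept)"])
  p_a <- sm["I(k^2)", "Pr(>|t|)"]
  p_b <- sm["k", "Pr(>|t|)"]
  structure(list(a = a, b = b, c = cc, p_a = p_a, p_b = p_b,
                 significant = is.finite(p_a) && p_a < p_threshold,
                 residuals = unname(residuals(fit)), n = nrow(records)),
            class = "gw_quadfit")
}

#' Optimal number of training generations from a quadratic fit
#'
#' The vertex `-b/(2a)` of the fitted parabola, capped at `k_max` because
#' a windowed design can only reach `k_max` generations back. A convex or
#' degenerate fit (`a >= 0`) has no interior maximum and returns a flagged
#' status instead of a number; a non-significant quadratic still yields a
#' numeric optimum but carries the flag from the fit.
#'
#' @param fit A [fit_quadratic()] result.
#' @param k_max Cap on the optimum (default 8).
#' @return List of class `gw_optimum`: `k_star` (numeric or `NA`),
#'   `status` (`"ok"`, `"capped"`, `"no interior maximum"`), and
#'   `significant` copied from the fit.
#' @export
optimal_k <- function(fit, k_max = 8) {
  stopifnot(inherits(fit, "gw_quadfit"))
  if (!is.finite(fit$a) || fit$a >= 0) {
    return(structure(list(k_star = NA_real_, status = "no interior maximum",
                          significant = fit$significant),
                     class = "gw_optimum"))
  }
  vertex <- -fit$b / (2 * fit$a)
  structure(list(k_star = min(vertex, k_max),
                 status = if (vertex > k_max) "capped" else "ok",
                 significant = fit$significant),
            class = "gw_optimum")
}

#' Correlate per-trait optima with heritability
#'
#' Pearson correlation between the optimal numbers of training generations
#' and trait heritabilities (pedigree- or marker-based), matched by trait
#' name.
#'
#' @param optima Named numeric vector of per-trait optima.
#' @param h2 Named numeric vector of per-trait heritabilities.
#' @return Pearson correlation (single numeric).
#' @export
correlate_optima_with_h2 <- function(optima, h2) {
  common <- intersect(names(optima), names(h2))
  x <- optima[common]; y <- h2[common]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop_genwin("need >= 3 traits with both an optimum and an h2")
  if (sd(x) == 0 || sd(y) == 0)
    stop_genwin("undefined correlation: constant optima or constant h2")
  cor(x, y)
}

#' Per-trait optima table from a sweep result
#'
#' Convenience wrapper: for each trait (one method), fits the quadratic and
#' derives the capped optimum.
#'
#' @param sweep Data frame from [run_generation_sweep()].
#' @param method Method whose records to use (default `"bayesb"`).
#' @param k_max Cap passed to [optimal_k()].
#' @return Data frame (`trait`, `a`, `b`, `c`, `p_a`, `p_b`, `k_star`,
#'   `status`, `significant`).
#' @export
optima_by_trait <- function(sweep, method = "bayesb", k_max = 8) {
  sub <- sweep[sweep$method == method, , drop = FALSE]
  traits <- unique(sub$trait)
  rows <- lapply(traits, function(tr) {
    fit <- fit_quadratic(sub[sub$trait == tr, , drop = FALSE])
    opt <- optimal_k(fit, k_max = k_max)
    data.frame(trait = tr, a = fit$a, b = fit$b, c = fit$c,
               p_a = fit$p_a, p_b = fit$p_b, k_star = opt$k_star,
               status = opt$status, significant = opt$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
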