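# Heidelberger-Welch convergence diagnostic for MCMC chains.

# Spectral density of a chain at frequency zero, from an AR fit selected by
# AIC: S(0) = sigma2_pred / (1 - sum(phi))^2. Used for the asymptotic
# variance of the chain mean.
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (var(x) == 0) return(0)
  fit <- tryCatch(ar(x, aic = TRUE, order.max = min(30L, length(x) %/% 4L)),
                  error = function(e) NULL)
  if (is.null(fit)) return(var(x))
  if (fit$order == 0L) fit$var.pred else fit$var.pred / (1 - sum(fit$ar))^2
}

# Asymptotic distribution function of the Cramer-von Mises statistic
# (first terms of the standard Bessel-function series; adequate for the
# p-values used here).
pcvm <- function(q) {
  q <- pmax(q, 1e-10)
  tot <- numeric(length(q))
  for (k in 0:3) {
    z <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(k + 1) * pi^1.5 * sqrt(q))
    x <- (4 * k + 1)^2 / (16 * q)
    term <- ifelse(x > 700, 0, z * exp(-x) * besselK(x, 0.25))
    tot <- tot + term
  }
  pmin(pmax(tot, 0), 1)
}

#' Heidelberger-Welch stationarity and half-width diagnostic
#'
#' Stationarity: a Cramer-von Mises test on the standardized cumulative-sum
#' (Brownian-bridge) process of the chain, using a spectral estimate of the
#' asymptotic variance from the second half of the chain; if the test
#' rejects, the first 10% of the chain is discarded and the test repeated,
#' until at most 40% of the chain has been discarded. Half-width: the
#' `1 - alpha` confidence-interval
#' half-width of the mean of the retained part, again from the spectral
#' variance estimate, must be below `halfwidth_frac` times the absolute
#' mean.
#'
#' @param chain Numeric vector of MCMC draws (length >= 100).
#' @param alpha Test level for both parts (default 0.05).
#' @param halfwidth_frac Maximum tolerated ratio of CI half-width to
#'   absolute mean (default 0.1).
#' @return List of class `gw_heidel`: `stationarity_passed`,
#'   `start_iteration`, `cvm_pvalue`, `mean`, `halfwidth`,
#'   `halfwidth_passed`, and `status` (`"ok"`, `"nonstationary"` or
#'   `"degenerate"` for a zero-variance chain).
#' @export
heidelberger_welch <- function(chain, alpha = 0.05, halfwidth_frac = 0.1) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100L) stop_genwin("heidelberger_welch: chain length must be >= 100")
  if (var(chain) == 0) {
    return(structure(list(stationarity_passed = NA, start_iteration = NA,
                          cvm_pvalue = NA_real_, mean = chain[1L],
                          halfwidth = 0, halfwidth_passed = NA,
                          status = "degenerate"),
                     class = "gw_heidel"))
  }
  s0 <- spectrum0_ar(chain[(n %/% 2 + 1L):n])
  passed <- FALSE; start <- 1L; pval <- NA_real_
  for (frac in seq(0, 0.4, by = 0.1)) {
    start <- floor(frac * n) + 1L
    y <- chain[start:n]
    ny <- length(y)
    b <- cumsum(y) - mean(y) * seq_len(ny)
    cvm <- sum(b^2 / (ny * s0)) / ny
    pval <- 1 - pcvm(cvm)
    if (pval > alpha) { passed <- TRUE; break }
  }
  y <- chain[start:n]
  s0y <- spectrum0_ar(y)
  hw <- qnorm(1 - alpha / 2) * sqrt(s0y / length(y))
  m <- mean(y)
  structure(list(stationarity_passed = passed, start_iteration = start,
                 cvm_pvalue = pval, mean = m, halfwidth = hw,
                 halfwidth_passed = is.finite(m) && abs(m) > 0 &&
                   hw / abs(m) < halfwidth_frac,
                 status = if (passed) "ok" else "nonstationary"),
            class = "gw_heidel")
}

#' @export
print.gw_heidel <- function(x, ...) {
  cat(sprintf("<gw_heidel> status: %s", x$status))
  if (x$status != "degenerate")
    cat(sprintf(" (start %d, CvM p = %.3f, mean %.4g, halfwidth %.4g, halfwidth %s)",
                x$start_iteration, x$cvm_pvalue, x$mean, x$halfwidth,
                if (isTRUE(x$halfwidth_passed)) "ok" else "too wide"))
  cat("\n")
  invisible(x)
}
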