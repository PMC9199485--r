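#' Bootstrap mediation of transfer through participation-coefficient change
#'
#' Estimates the standardized paths of the simple mediation model with
#' trained-domain change x, PC change m as mediator, and transfer-domain
#' change y as outcome: `a` (x to m), `b` (m to y adjusting x), `c` (total
#' x to y), `c_prime` (direct), and the indirect effect `a * b`. Variables
#' are z-standardized with the analysis sample's mean and SD; bootstrap
#' replicates resample subjects (x, m, y jointly) and refit on the original
#' scaling, so paths stay comparable across replicates. The indirect
#' effect's confidence interval is the bootstrap percentile interval by
#' default (a bias-corrected-accelerated interval is available); mediation
#' is tested regardless of the significance of the total effect, since a
#' near-zero total effect can mask opposing indirect paths.
#'
#' The OLS decomposition `c = c_prime + a * b` holds exactly for the point
#' estimates and within every bootstrap replicate.
#'
#' @param x,m,y Numeric vectors: independent variable, mediator, outcome
#'   (n >= 10).
#' @param n_boot Bootstrap replicates (default 5000; < 100 warns).
#' @param ci Confidence level (default 0.95).
#' @param seed Optional seed; identical seeds give identical intervals.
#' @param method `"percentile"` (default) or `"bca"`.
#' @param standardize Z-standardize inputs (default TRUE).
#' @return List of class `mediation_result`: paths `a`, `b`, `c`,
#'   `c_prime`, `indirect`, `ci_lower`, `ci_upper`, `significant` (CI
#'   excludes 0), plus bootstrap settings and the replicate indirect
#'   effects in `boot_indirect`.
#' @export
fit_mediation <- function(x, m, y, n_boot = 5000L, ci = 0.95, seed = NULL,
                          method = c("percentile", "bca"),
                          standardize = TRUE) {
  method <- match.arg(method)
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("x, m, y must be paired")
  if (n < 10L) stop("mediation needs n >= 10")
  if (sd(x) == 0 || sd(m) == 0 || sd(y) == 0)
    stop("degenerate variance in x, m or y")
  if (n_boot < 100L) warning("n_boot < 100 gives unstable intervals")
  if (!is.null(seed)) set.seed(seed)
  if (standardize) {
    x <- (x - mean(x)) / sd(x)
    m <- (m - mean(m)) / sd(m)
    y <- (y - mean(y)) / sd(y)
  }
  est <- mediation_paths(x, m, y)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boot <- mediation_paths_boot(x, m, y, idx)
  probs <- c((1 - ci) / 2, 1 - (1 - ci) / 2)
  ci_bounds <- if (method == "percentile") {
    quantile(boot$indirect, probs, names = FALSE)
  } else {
    bca_interval(boot$indirect, est["indirect"], x, m, y, probs)
  }
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 c = unname(est["c"]), c_prime = unname(est["c_prime"]),
                 indirect = unname(est["indirect"]),
                 ci_lower = ci_bounds[1L], ci_upper = ci_bounds[2L],
                 significant = ci_bounds[1L] > 0 || ci_bounds[2L] < 0,
                 ci = ci, n_boot = as.integer(n_boot), method = method,
                 seed = seed, n = n, standardized = standardize,
                 boot_indirect = boot$indirect, boot = boot),
            class = "mediation_result")
}

# point-estimate paths from three OLS fits
mediation_paths <- function(x, m, y) {
  a <- cov(x, m) / var(x)
  c_tot <- cov(x, y) / var(x)
  xm <- cbind(1, x, m)
  cf <- qr.coef(qr(xm), y)
  c(a = a, b = unname(cf[3L]), c = c_tot, c_prime = unname(cf[2L]),
    indirect = a * unname(cf[3L]))
}

# vectorised bootstrap: closed-form OLS paths for every resample column
mediation_paths_boot <- function(x, m, y, idx) {
  n <- nrow(idx)
  Xb <- matrix(x[idx], n); Mb <- matrix(m[idx], n); Yb <- matrix(y[idx], n)
  mx <- colMeans(Xb); mm <- colMeans(Mb); my <- colMeans(Yb)
  Sxx <- colMeans(Xb^2) - mx^2
  Smm <- colMeans(Mb^2) - mm^2
  Sxm <- colMeans(Xb * Mb) - mx * mm
  Sxy <- colMeans(Xb * Yb) - mx * my
  Smy <- colMeans(Mb * Yb) - mm * my
  a <- Sxm / Sxx
  det <- Sxx * Smm - Sxm^2
  b <- (Sxx * Smy - Sxm * Sxy) / det
  c_prime <- (Smm * Sxy - Sxm * Smy) / det
  c_tot <- Sxy / Sxx
  list(a = a, b = b, c = c_tot, c_prime = c_prime, indirect = a * b)
}

# bias-corrected and accelerated bootstrap interval for the indirect effect
bca_interval <- function(boot_stat, est, x, m, y, probs) {
  z0 <- qnorm(mean(boot_stat < est))
  n <- length(x)
  jack <- vapply(seq_len(n), function(i)
    mediation_paths(x[-i], m[-i], y[-i])[["indirect"]], numeric(1))
  jm <- mean(jack)
  acc <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
  zq <- qnorm(probs)
  adj <- pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
  quantile(boot_stat, adj, names = FALSE)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation (standardized paths, case-resampling bootstrap)\n")
  cat(sprintf("  x -> m            a       = %7.4f\n", x$a))
  cat(sprintf("  m -> y | x        b       = %7.4f\n", x$b))
  cat(sprintf("  x -> y direct     c'      = %7.4f\n", x$c_prime))
  cat(sprintf("  x -> y total      c       = %7.4f\n", x$c))
  cat(sprintf("  indirect (a*b)            = %7.4f\n", x$indirect))
  cat(sprintf("  %d%% %s CI [%0.4f, %0.4f]%s  (n = %d, %d bootstraps)\n",
              round(100 * x$ci), x$method, x$ci_lower, x$ci_upper,
              if (x$significant) " *" else "", x$n, x$n_boot))
  invisible(x)
}
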