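#' Count-based yield estimate with Bernoulli standard error
#'
#' Yield is the number of desired product structures divided by the total
#' number of structures counted in AFM fields, treated as a Bernoulli
#' probability. The standard error uses the convention
#' `se = p * sqrt(1 - p) / sqrt(n)` (note: not the textbook binomial
#' `sqrt(p (1 - p) / n)`, which is available as [yield_se_binomial()]); with
#' this convention 1 product among 12 arrays gives 8.3 +/- 2.3%.
#'
#' @param n_product Number of desired product structures (0..n_total).
#' @param n_total Total structures counted (>= 1).
#' @return An object of class `yield_estimate` with fields `p`, `n`, `se`.
#' @examples
#' yield_estimate(1, 12)   # 8.3 +/- 2.3 %
#' @export
yield_estimate <- function(n_product, n_total) {
  n_product <- as.integer(n_product); n_total <- as.integer(n_total)
  if (is.na(n_total) || n_total < 1L) stop("n_total must be >= 1")
  if (is.na(n_product) || n_product < 0L || n_product > n_total)
    stop("need 0 <= n_product <= n_total")
  p <- n_product / n_total
  se <- p * sqrt(1 - p) / sqrt(n_total)
  structure(list(p = p, n = n_total, se = se), class = "yield_estimate")
}

#' Textbook binomial standard error
#'
#' The conventional `sqrt(p (1 - p) / n)`, provided as a clearly separate
#' alternative to the convention used by [yield_estimate()].
#'
#' @param p Estimated proportion.
#' @param n Number of trials.
#' @return Standard error.
#' @export
yield_se_binomial <- function(p, n) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  sqrt(p * (1 - p) / n)
}

#' @export
print.yield_estimate <- function(x, ...) {
  cat(sprintf("yield: %.1f +/- %.1f %% (n = %d)\n", 100 * x$p, 100 * x$se, x$n))
  invisible(x)
}
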