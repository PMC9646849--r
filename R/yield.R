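#' Measurement yield proportion
#'
#' The yield is `x / n`, where `n` is the number of studies with all
#' three human reads and `x` the subset for which the automated
#' workflow also emitted a measurement (it may withhold output on
#' quality grounds).
#'
#' @param x Number of studies with three human reads and an automated
#'   read.
#' @param n Number of studies with three human reads, >= 1.
#' @return A proportion in `[0, 1]`.
#' @export
yield_proportion <- function(x, n) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.numeric(x) || x < 0 || x > n) {
    stop("x must satisfy 0 <= x <= n", call. = FALSE)
  }
  x / n
}

#' Binomial-quantile interval for a yield
#'
#' Interval from the `q_low` and `q_high` quantiles of the
#' `Binomial(n, x/n)` distribution, each divided by `n`.  The quantile
#' convention is the usual "smallest k with CDF >= q".  Note this is a
#' quantile band of the fitted binomial, not a coverage-calibrated
#' confidence interval; alternative quantile levels can be supplied.
#'
#' @inheritParams yield_proportion
#' @param q_low,q_high Quantile levels (defaults 0.05 and 0.95).
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
yield_ci <- function(x, n, q_low = 0.05, q_high = 0.95) {
  p <- yield_proportion(x, n)
  stopifnot(q_low >= 0, q_high <= 1, q_low <= q_high)
  c(ci_low = qbinom(q_low, n, p) / n,
    ci_high = qbinom(q_high, n, p) / n)
}

#' Unweighted cross-parameter average yield
#'
#' @param results A tibble of yield results with a `proportion` column
#'   (see [yield_table()]), or a bare numeric vector of proportions.
#' @return The unweighted mean proportion.
#' @export
average_yield <- function(results) {
  p <- if (is.data.frame(results)) results$proportion else results
  if (length(p) == 0L) stop("no yield results supplied", call. = FALSE)
  mean(p)
}

#' Per-parameter yield table
#'
#' For every parameter present in the table: the number of studies with
#' three human reads (`n_triples`), the subset with an automated read
#' (`n_quads`), the yield proportion and its binomial quantile
#' interval.
#'
#' @param table A validated measurement table.
#' @param q_low,q_high Quantile levels for the interval.
#' @return A tibble with columns `parameter`, `n_triples`, `n_quads`,
#'   `proportion`, `ci_low`, `ci_high`, one row per parameter, ordered
#'   by parameter name.
#' @export
yield_table <- function(table, q_low = 0.05, q_high = 0.95) {
  pars <- sort(unique(table$parameter))
  rows <- lapply(pars, function(p) {
    n <- nrow(human_triples(table, p))
    x <- nrow(complete_quadruples(table, p))
    if (n == 0L) {
      return(tibble::tibble(parameter = p, n_triples = 0L, n_quads = x,
                            proportion = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_))
    }
    ci <- yield_ci(x, n, q_low, q_high)
    tibble::tibble(parameter = p, n_triples = n, n_quads = x,
                   proportion = x / n,
                   ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]])
  })
  dplyr::bind_rows(rows)
}
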