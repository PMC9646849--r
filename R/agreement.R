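#' Complete-case readings matrix for a reader set
#'
#' @param table A validated measurement table.
#' @param parameter Parameter name.
#' @param readers Character vector (length >= 2) drawn from
#'   `R1, R2, R3, AUTO`.
#' @return A numeric matrix (studies x readers) of complete cases,
#'   study ids as row names, ordered by study id.
#' @export
readings_matrix <- function(table, parameter,
                            readers = c("R1", "R2", "R3", "AUTO")) {
  stopifnot(length(readers) >= 2L, all(readers %in% READER_LABELS),
            !anyDuplicated(readers))
  wide <- wide_reads(table, parameter)
  m <- as.matrix(wide[readers])
  rownames(m) <- wide$study_id
  m[stats::complete.cases(m), , drop = FALSE]
}

check_matrix <- function(m, min_n = 1L) {
  m <- as.matrix(m)
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("readings matrix must be numeric with no missing cells",
         call. = FALSE)
  }
  if (ncol(m) < 2L) stop("need at least 2 readers", call. = FALSE)
  if (nrow(m) < min_n) {
    stop("need at least ", min_n, " studies", call. = FALSE)
  }
  m
}

## Two-way crossed ANOVA mean squares (studies x readers, one
## observation per cell).
anova_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rmeans <- rowMeans(m)
  cmeans <- colMeans(m)
  msr <- k * sum((rmeans - grand)^2) / (n - 1)
  msc <- n * sum((cmeans - grand)^2) / (k - 1)
  resid <- m - outer(rmeans, rep(1, k)) - outer(rep(1, n), cmeans) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' from the crossed ANOVA mean squares:
#' \deqn{\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}
#'   {MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-study, \eqn{MS_C} the between-reader and
#' \eqn{MS_E} the residual mean square.  Readers are treated as a
#' random sample and systematic reader offsets count against agreement.
#'
#' @param m Numeric matrix, studies x readers, no missing cells,
#'   n >= 2.
#' @return A scalar <= 1.
#' @export
icc <- function(m) {
  m <- check_matrix(m, min_n = 2L)
  ms <- anova_ms(m)
  denom <- ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse)
  if (denom == 0) {
    stop("total variance is zero: ICC undefined", call. = FALSE)
  }
  (ms$msr - ms$mse) / denom
}

#' Mean absolute pairwise deviation
#'
#' Mean over studies of the mean absolute difference over all unordered
#' reader pairs, in measurement units.
#'
#' @inheritParams icc
#' @return A non-negative scalar.
#' @export
mad_pairwise <- function(m) {
  m <- check_matrix(m, min_n = 1L)
  pairs <- utils::combn(ncol(m), 2L)
  d <- abs(m[, pairs[1, ], drop = FALSE] - m[, pairs[2, ], drop = FALSE])
  mean(rowMeans(d))
}

#' Within-patient coefficient of variation (percent)
#'
#' Root mean over studies of the squared per-study CV:
#' \eqn{100\sqrt{\mathrm{mean}_i(s_i^2/m_i^2)}} with \eqn{s_i^2} the
#' within-study sample variance across readers and \eqn{m_i} the
#' within-study mean.  Scale-invariant.
#'
#' @inheritParams icc
#' @return A non-negative percentage.
#' @export
wcv <- function(m) {
  m <- check_matrix(m, min_n = 1L)
  means <- rowMeans(m)
  if (any(means == 0)) {
    stop("within-study mean of zero: wCV undefined", call. = FALSE)
  }
  vars <- apply(m, 1L, var)
  100 * sqrt(mean(vars / means^2))
}

#' Residual RMSE after additive study and reader effects
#'
#' Root mean square of the double-centred residuals
#' \eqn{y_{ij} - \bar y_{i.} - \bar y_{.j} + \bar y_{..}} with
#' \eqn{(n-1)(k-1)} degrees of freedom; exactly zero when agreement is
#' additive-perfect (each reader a constant offset from the others).
#'
#' @inheritParams icc
#' @return A non-negative scalar in measurement units.
#' @export
rmse_twoway <- function(m) {
  m <- check_matrix(m, min_n = 2L)
  sqrt(anova_ms(m)$mse)
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{\mathrm{CCC} = \frac{2\,\mathrm{cov}(x,y)}
#'   {\mathrm{var}(x) + \mathrm{var}(y) + (\bar x - \bar y)^2}}
#' with population (1/n) moments.  Combines correlation with location
#' and scale shift; satisfies \eqn{|\mathrm{CCC}| \le |r|}.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A scalar in `[-1, 1]`.
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) {
    stop("both series constant and equal: CCC undefined", call. = FALSE)
  }
  2 * cxy / denom
}

#' Bland-Altman limits of agreement
#'
#' Centre is the mean difference `x - y`; the half-width is
#' `1.96 * SD` of the differences (sample SD, n-1 denominator), so the
#' limits are `center +/- halfwidth`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A list with `center`, `halfwidth`, and `points` (a tibble of
#'   per-study pair means and differences for plotting).
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 2L) stop("need at least 2 paired values", call. = FALSE)
  d <- x - y
  list(
    center = mean(d),
    halfwidth = 1.96 * sd(d),
    points = tibble::tibble(mean = (x + y) / 2, difference = d)
  )
}

#' Coverage probability within a tolerance
#'
#' Fraction of studies whose paired absolute difference is at most
#' `delta` (in measurement units).
#'
#' @param x,y Numeric vectors of equal length >= 1.
#' @param delta Tolerance, > 0.
#' @return A scalar in `[0, 1]`.
#' @export
coverage_probability <- function(x, y, delta) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("delta must be a positive tolerance", call. = FALSE)
  }
  mean(abs(x - y) <= delta)
}

boxplot_summary <- function(v) {
  if (length(v) == 0L) {
    return(tibble::tibble(n = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_, whisker_low = NA_real_,
                          whisker_high = NA_real_))
  }
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- min(v[v >= q[1] - 1.5 * iqr])
  hi <- max(v[v <= q[3] + 1.5 * iqr])
  tibble::tibble(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = lo, whisker_high = hi)
}

#' Relative absolute differences, human-human versus automated-human
#'
#' For each complete quadruple, the human-human distribution pools
#' \eqn{|h_j - h_k| / \frac{h_j + h_k}{2}} over the three human pairs,
#' and the automated-human distribution pools
#' \eqn{|a - h_j| / \frac{a + h_j}{2}} over the three readers.  Pairs
#' whose mean is zero are excluded and counted.
#'
#' @inheritParams complete_quadruples
#' @return A list with `human_human` and `auto_human` (pooled numeric
#'   vectors), `summary` (a two-row box-plot summary tibble: median,
#'   quartiles, 1.5 IQR whiskers), and `n_excluded`.
#' @export
relative_absolute_differences <- function(table, parameter) {
  quads <- complete_quadruples(table, parameter)
  h <- as.matrix(quads[HUMAN_READERS])
  a <- quads$AUTO
  rad <- function(u, v) {
    pm <- (u + v) / 2
    keep <- pm != 0
    list(values = abs(u - v)[keep] / pm[keep], excluded = sum(!keep))
  }
  hh <- list(rad(h[, 1], h[, 2]), rad(h[, 1], h[, 3]), rad(h[, 2], h[, 3]))
  ah <- list(rad(a, h[, 1]), rad(a, h[, 2]), rad(a, h[, 3]))
  pool <- function(l) unlist(lapply(l, `[[`, "values"), use.names = FALSE)
  n_excl <- sum(vapply(c(hh, ah), `[[`, numeric(1), "excluded"))
  hh_v <- pool(hh); ah_v <- pool(ah)
  summary <- dplyr::bind_rows(
    dplyr::mutate(boxplot_summary(hh_v), comparison = "human-human",
                  .before = 1),
    dplyr::mutate(boxplot_summary(ah_v), comparison = "auto-human",
                  .before = 1)
  )
  list(human_human = hh_v, auto_human = ah_v, summary = summary,
       n_excluded = n_excl)
}

#' Secondary-endpoint agreement report for one parameter
#'
#' Assembles the full battery on the complete cases of the chosen
#' reader set: ICC(2,1), mean absolute pairwise deviation, within-patient
#' CV, two-way residual RMSE across all readers in the set, plus the
#' pairwise metrics (CCC, Bland-Altman limits, coverage probability)
#' comparing the automated source against the per-study mean of the
#' three human reads.  Pairwise metrics are `NA` when the reader set
#' excludes `AUTO`.
#'
#' @inheritParams complete_quadruples
#' @param readers Reader set, e.g. `c("R1","R2","R3","AUTO")` or the
#'   human-only `c("R1","R2","R3")`.
#' @param cp_delta Tolerance for the coverage probability, in the
#'   parameter's units; no universal default exists, so it must be
#'   supplied.
#' @return A one-row tibble: `parameter`, `reader_set`, `n`, `icc`,
#'   `mad`, `wcv`, `rmse`, `ccc`, `loa_center`, `loa_halfwidth`, `cp`,
#'   `cp_delta`.
#' @export
agreement_report <- function(table, parameter,
                             readers = c("R1", "R2", "R3", "AUTO"),
                             cp_delta = NULL) {
  m <- readings_matrix(table, parameter, readers)
  if (nrow(m) < 2L) {
    stop("fewer than 2 complete cases for reader set {",
         paste(readers, collapse = ","), "}", call. = FALSE)
  }
  has_auto <- "AUTO" %in% readers
  if (has_auto) {
    quads <- complete_quadruples(table, parameter)
    href <- rowMeans(as.matrix(quads[HUMAN_READERS]))
    auto <- quads$AUTO
    ba <- bland_altman(auto, href)
    cp <- if (is.null(cp_delta)) NA_real_ else {
      coverage_probability(auto, href, cp_delta)
    }
    ccc_v <- ccc(auto, href)
  } else {
    ba <- list(center = NA_real_, halfwidth = NA_real_)
    cp <- NA_real_
    ccc_v <- NA_real_
  }
  tibble::tibble(
    parameter = parameter,
    reader_set = paste(readers, collapse = "+"),
    n = nrow(m),
    icc = icc(m),
    mad = mad_pairwise(m),
    wcv = wcv(m),
    rmse = rmse_twoway(m),
    ccc = ccc_v,
    loa_center = ba$center,
    loa_halfwidth = ba$halfwidth,
    cp = cp,
    cp_delta = if (is.null(cp_delta)) NA_real_ else cp_delta
  )
}
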