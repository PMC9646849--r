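## Per-study squared-difference sums. For quadruples (R1,R2,R3,AUTO):
##   tr_i = sum_j (a_i - h_ij)^2 over the 3 humans
##   rr_i = sum_{j<k} (h_ij - h_ik)^2 over the 3 human pairs
## Q_TR = mean(tr)/3 and Q_RR = mean(rr)/3; precomputing the sums makes
## bootstrap replicates a single indexed mean.
quad_sums <- function(quads) {
  h <- as.matrix(quads[HUMAN_READERS])
  a <- quads$AUTO
  stopifnot(is.numeric(h), is.numeric(a))
  tr <- (a - h[, 1])^2 + (a - h[, 2])^2 + (a - h[, 3])^2
  rr <- (h[, 1] - h[, 2])^2 + (h[, 1] - h[, 3])^2 + (h[, 2] - h[, 3])^2
  list(tr = tr, rr = rr)
}

#' Mean squared test-versus-reference difference (Q_TR)
#'
#' Mean over all (study, human reader) combinations of the squared
#' difference between the automated read and that human read:
#' \eqn{Q_{TR} = \frac{1}{3n}\sum_i\sum_{j=1}^{3}(a_i - h_{ij})^2}.
#'
#' @param quads Tibble of complete quadruples with columns `R1`, `R2`,
#'   `R3`, `AUTO` (see [complete_quadruples()]).
#' @return A non-negative scalar in squared measurement units.
#' @export
q_tr <- function(quads) {
  if (NROW(quads) == 0L) stop("no quadruples supplied", call. = FALSE)
  mean(quad_sums(quads)$tr) / 3
}

#' Mean squared reference-versus-reference difference (Q_RR)
#'
#' Mean over all (study, unordered human pair) combinations of the
#' squared difference between two human reads:
#' \eqn{Q_{RR} = \frac{1}{3n}\sum_i\sum_{j<k}(h_{ij} - h_{ik})^2}.
#'
#' @param quads Tibble with columns `R1`, `R2`, `R3` (an `AUTO` column,
#'   if present, is ignored).
#' @return A non-negative scalar in squared measurement units.
#' @export
q_rr <- function(quads) {
  if (NROW(quads) == 0L) stop("no reader triples supplied", call. = FALSE)
  h <- as.matrix(quads[HUMAN_READERS])
  mean((h[, 1] - h[, 2])^2 + (h[, 1] - h[, 3])^2 + (h[, 2] - h[, 3])^2) / 3
}

#' Individual equivalence coefficient
#'
#' The scale-free interchangeability statistic
#' \deqn{\mathrm{IEC} = \frac{Q_{TR} - Q_{RR}}{Q_{RR}/2}.}
#' Its expected value is 0 when automated-versus-human differences have
#' the same variability as human-versus-human differences, negative when
#' the automated source disagrees with the humans less than the humans
#' disagree with each other, and equals \eqn{\gamma - 1} when the
#' automated within-patient error variance is \eqn{\gamma} times the
#' human one (no bias).  It is invariant under affine rescaling of the
#' measurements.
#'
#' @inheritParams q_tr
#' @return A dimensionless scalar.
#' @export
iec <- function(quads) {
  s <- quad_sums(quads)
  if (NROW(quads) == 0L) stop("no quadruples supplied", call. = FALSE)
  qrr <- mean(s$rr) / 3
  if (qrr == 0) {
    stop("Q_RR is zero: reference readers are degenerate, IEC undefined",
         call. = FALSE)
  }
  qtr <- mean(s$tr) / 3
  (qtr - qrr) / (qrr / 2)
}

#' IEC for an arbitrary test source against k reference readers
#'
#' Same statistic with Q_TR averaged over all (study, reference)
#' differences and Q_RR over all \eqn{\binom{k}{2}} reference pairs.
#' With three references and the automated source as test it reduces to
#' [iec()]; with `test` one human reader and the other two as
#' references it gives the reader-pair secondary analyses.
#'
#' @param test Numeric vector of test-source values, one per study.
#' @param refs Numeric matrix (n studies x k >= 2 reference readers),
#'   complete cases only.
#' @return A dimensionless scalar.
#' @export
generalized_iec <- function(test, refs) {
  refs <- as.matrix(refs)
  k <- ncol(refs)
  if (k < 2L) stop("need at least 2 reference readers", call. = FALSE)
  if (length(test) != nrow(refs)) {
    stop("test values and reference rows differ in length", call. = FALSE)
  }
  if (any(!is.finite(test)) || any(!is.finite(refs))) {
    stop("all values must be finite (complete cases only)", call. = FALSE)
  }
  qtr <- mean((test - refs)^2)
  pairs <- utils::combn(k, 2L)
  d2 <- (refs[, pairs[1, ], drop = FALSE] - refs[, pairs[2, ], drop = FALSE])^2
  qrr <- mean(d2)
  if (qrr == 0) {
    stop("Q_RR is zero: reference readers are degenerate, IEC undefined",
         call. = FALSE)
  }
  (qtr - qrr) / (qrr / 2)
}

#' Bootstrap non-inferiority test of the IEC
#'
#' Resamples studies (whole quadruples, never individual readers) with
#' replacement, `n_boot` replicates of the original size, and takes the
#' sample SD of the replicate IECs.  The 95% bound is the
#' normal-approximation `iec +/- 1.96 * sd_boot` around the
#' original-sample IEC, and the automated source is judged non-inferior
#' when `iec + 1.96 * sd_boot <= margin`.  Percentile 2.5%/97.5% bounds
#' are also reported for comparison but never drive the verdict.
#' Replicates whose resampled Q_RR is exactly zero are redrawn (and
#' counted) so `n_boot` is always honoured.
#'
#' @inheritParams q_tr
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; same seed and input give an identical
#'   result.
#' @param margin Non-inferiority margin for the upper bound
#'   (default 0.25, i.e. at most 25% excess within-patient error
#'   variance).
#' @param parameter Optional parameter label carried into the result.
#' @return An `iec_result` list: `parameter`, `n`, `q_tr`, `q_rr`,
#'   `iec`, `sd_boot`, `lower95`, `upper95`, `pct_lower95`,
#'   `pct_upper95`, `margin`, `noninferior`, `n_boot`, `n_redraws`,
#'   `seed`.
#' @export
bootstrap_iec <- function(quads, n_boot = 10000L, seed = 1L, margin = 0.25,
                          parameter = NA_character_) {
  n <- NROW(quads)
  if (n < 2L) stop("need at least 2 quadruples to bootstrap", call. = FALSE)
  if (n_boot < 2L) stop("n_boot must be at least 2", call. = FALSE)
  s <- quad_sums(quads)
  if (mean(s$rr) == 0) {
    stop("Q_RR is zero: reference readers are degenerate, IEC undefined",
         call. = FALSE)
  }
  point <- iec(quads)

  boot <- with_rng(seed, {
    reps <- numeric(n_boot)
    redraws <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        rr <- mean(s$rr[idx])
        if (rr > 0) break
        redraws <- redraws + 1L
      }
      tr <- mean(s$tr[idx])
      reps[b] <- (tr - rr) / (rr / 2)
    }
    list(reps = reps, redraws = redraws)
  })

  sd_boot <- sd(boot$reps)
  upper95 <- point + 1.96 * sd_boot
  pct <- unname(quantile(boot$reps, c(0.025, 0.975), type = 7))
  structure(list(
    parameter = parameter, n = n,
    q_tr = q_tr(quads), q_rr = q_rr(quads), iec = point,
    sd_boot = sd_boot,
    lower95 = point - 1.96 * sd_boot, upper95 = upper95,
    pct_lower95 = pct[1], pct_upper95 = pct[2],
    margin = margin,
    noninferior = noninferiority_decision(point, sd_boot, margin),
    n_boot = as.integer(n_boot), n_redraws = boot$redraws,
    seed = as.integer(seed)
  ), class = "iec_result")
}

#' @export
print.iec_result <- function(x, ...) {
  cat(sprintf(
    "IEC non-inferiority test%s\n  n = %d quadruples, %d bootstrap replicates (seed %d)\n",
    if (is.na(x$parameter)) "" else paste0(" [", x$parameter, "]"),
    x$n, x$n_boot, x$seed))
  cat(sprintf("  Q_TR = %.4g, Q_RR = %.4g\n", x$q_tr, x$q_rr))
  cat(sprintf("  IEC = %.4f (SD %.4f), 95%% bound [%.4f, %.4f]\n",
              x$iec, x$sd_boot, x$lower95, x$upper95))
  cat(sprintf("  verdict vs margin %.2f: %s\n", x$margin,
              if (x$noninferior) "NON-INFERIOR" else "inferior"))
  invisible(x)
}

#' Non-inferiority verdict from an IEC point estimate and SD
#'
#' The automated source is non-inferior when
#' `iec + 1.96 * sd <= margin`; the boundary counts as non-inferior
#' because inferiority is declared only when the bound strictly exceeds
#' the margin.
#'
#' @param iec IEC point estimate.
#' @param sd Bootstrap SD of the IEC (>= 0).
#' @param margin Non-inferiority margin (default 0.25).
#' @return `TRUE` (non-inferior) or `FALSE` (inferior).
#' @export
noninferiority_decision <- function(iec, sd, margin = 0.25) {
  if (!is.numeric(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  iec + 1.96 * sd <= margin
}
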