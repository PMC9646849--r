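#' Power-simulation configuration
#'
#' @param generator A [generator_config()] template; its `n_studies` is
#'   overridden by the grid and its error SDs rescaled so the
#'   automated-to-human variance ratio equals `gamma`.
#' @param n_grid Ascending study counts to evaluate.
#' @param gamma Variance ratio \eqn{\sigma_T^2 / \sigma_R^2} under
#'   which power is estimated (> 0).
#' @param margin Non-inferiority margin (> 0).
#' @param n_sims Simulated trials per grid point (>= 1).
#' @param n_boot_inner Bootstrap replicates inside each simulated trial;
#'   deliberately smaller than the 10000 of a confirmatory analysis
#'   (default 500) — the bootstrap SD estimate is unbiased enough at
#'   this size for power estimation and the loop stays desk-scale.
#' @param seed Base seed; all per-trial seeds derive from it.
#' @param common_random_numbers If `TRUE` (default), trial t reuses the
#'   same seed across grid points so the power curve is monotone up to
#'   genuine sample-size effects rather than simulation noise.
#' @return A `power_config` list.
#' @export
power_config <- function(generator = generator_config(),
                         n_grid = c(150L, 300L, 600L),
                         gamma = 1, margin = 0.25,
                         n_sims = 200L, n_boot_inner = 500L,
                         seed = 1L, common_random_numbers = TRUE) {
  stopifnot(n_sims >= 1, n_boot_inner >= 2, margin > 0, gamma > 0,
            length(n_grid) >= 1, !is.unsorted(n_grid))
  generator <- as_generator_config(generator)
  if (generator$sigma_r <= 0) {
    stop("degenerate generator: sigma_r must be > 0 for power simulation",
         call. = FALSE)
  }
  structure(list(generator = generator, n_grid = as.integer(n_grid),
                 gamma = gamma, margin = margin,
                 n_sims = as.integer(n_sims),
                 n_boot_inner = as.integer(n_boot_inner),
                 seed = as.integer(seed),
                 common_random_numbers = common_random_numbers),
            class = "power_config")
}

#' Estimate power of the IEC non-inferiority test at one sample size
#'
#' Monte-Carlo estimate of the probability that the bootstrap upper 95%
#' bound of the IEC falls at or below the margin, when the automated
#' error variance truly is `gamma` times the human one.  Each simulated
#' trial generates `n` studies from the configured generator, runs
#' [bootstrap_iec()] with the reduced inner bootstrap, and records
#' success.
#'
#' @param config A [power_config()].
#' @param n Study count for this run.
#' @return A one-row tibble: `n`, `gamma`, `power`, `mc_se`
#'   (`sqrt(power (1-power) / n_sims)`), `n_sims`.
#' @export
estimate_power <- function(config, n) {
  stopifnot(inherits(config, "power_config"), n >= 2)
  gen <- config$generator
  gen$n_studies <- as.integer(n)
  gen$sigma_t <- sqrt(config$gamma) * gen$sigma_r
  successes <- 0L
  for (t in seq_len(config$n_sims)) {
    trial_seed <- derive_seed(config$seed, t)
    gen$seed <- trial_seed
    dat <- generate_dataset(gen)
    quads <- complete_quadruples(dat$table, gen$parameter)
    if (nrow(quads) < 2L) next
    res <- bootstrap_iec(quads, n_boot = config$n_boot_inner,
                         seed = derive_seed(trial_seed, 1L),
                         margin = config$margin)
    if (res$noninferior) successes <- successes + 1L
  }
  power <- successes / config$n_sims
  tibble::tibble(n = as.integer(n), gamma = config$gamma, power = power,
                 mc_se = sqrt(power * (1 - power) / config$n_sims),
                 n_sims = config$n_sims)
}

#' Smallest sample size on the grid reaching a target power
#'
#' Evaluates [estimate_power()] across `config$n_grid` (with common
#' random numbers across grid points when configured) and returns the
#' first grid value whose estimated power reaches the target, together
#' with the whole power curve.
#'
#' @param config A [power_config()].
#' @param target_power Required power in `[0, 1]` (a target above 1 can
#'   never be reached and yields `n = NA`).
#' @return A list with `n` (the chosen sample size, or `NA` if no grid
#'   value reaches the target), `reached` (logical), `target_power`,
#'   and `curve` (tibble of per-grid-point power results).
#' @export
sample_size_search <- function(config, target_power = 0.8) {
  stopifnot(inherits(config, "power_config"))
  cfg <- config
  curve <- dplyr::bind_rows(lapply(cfg$n_grid, function(n) {
    if (!cfg$common_random_numbers) {
      cfg$seed <- derive_seed(cfg$seed, match(n, cfg$n_grid))
    }
    estimate_power(cfg, n)
  }))
  hit <- which(curve$power >= target_power)
  list(
    n = if (length(hit)) curve$n[hit[1L]] else NA_integer_,
    reached = length(hit) > 0L,
    target_power = target_power,
    curve = curve
  )
}
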