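## Seeded RNG scope: evaluates expr under the given seed and restores the
## caller's RNG state, so library code never perturbs user scripts.
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Deterministic per-parameter sub-seed, kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 7919 * as.double(index)) %% 2147483629)
}

#' Configuration of the synthetic multi-reader generator
#'
#' Encodes the generative model the interchangeability analysis assumes:
#' a shared true value per study, independent additive human reader
#' errors, an automated read with its own error variance and systematic
#' bias, and a confidence score that gates whether the automated read is
#' emitted at all.
#'
#' The model for study \eqn{i} and human reader \eqn{j}:
#' \deqn{\mu_i \sim N(\mathrm{truth\_mean}, \mathrm{truth\_sd}^2)}
#' \deqn{y_{ij} = \mu_i + \mathrm{reader\_bias}_j + e_{ij}, \quad
#'       e_{ij} \sim N(0, \sigma_R^2)}
#' \deqn{a_i = \mu_i + \mathrm{auto\_bias} + u_i, \quad
#'       u_i \sim N(0, \sigma_T^2)}
#' The automated confidence score is
#' \eqn{c_i = 1 - \Phi(|u_i|/\sigma_T) + N(0,
#' \mathrm{confidence\_noise\_sd}^2)} clipped to \eqn{[0,1]}, and the
#' automated record is emitted only when \eqn{c_i \ge \tau}
#' (`confidence_threshold`).  With zero confidence noise the gate is
#' missing-not-at-random: exactly the largest automated errors are
#' suppressed, and realized yield equals \eqn{1 - 2\tau} in expectation.
#' A large `confidence_noise_sd` turns the gate effectively
#' missing-completely-at-random, which is what clean parameter-recovery
#' tests want.  Each human read is independently dropped with
#' probability `p_missing_human`.
#'
#' @param parameter Parameter name.
#' @param n_studies Number of studies (>= 1).
#' @param truth_mean,truth_sd Between-study distribution of the true
#'   value, in the parameter's units.
#' @param sigma_r Human reader error SD (>= 0), shared by the three
#'   readers.
#' @param sigma_t Automated error SD (>= 0).
#' @param auto_bias Systematic offset of the automated source.
#' @param reader_biases Numeric triple of human reader offsets.
#' @param p_missing_human Probability in `[0, 1]` that a given human
#'   read is absent.
#' @param confidence_threshold Gate \eqn{\tau} in `[0, 1]`.
#' @param confidence_noise_sd SD (>= 0) of the noise blurring the
#'   confidence score.
#' @param seed Integer seed; same seed, same table, bit for bit.
#' @return A `generator_config` list.
#' @export
generator_config <- function(parameter = "LVEF MOD biplane",
                             n_studies = 600L,
                             truth_mean = 35, truth_sd = 10,
                             sigma_r = 5, sigma_t = 5,
                             auto_bias = 0,
                             reader_biases = c(0, 0, 0),
                             p_missing_human = 0,
                             confidence_threshold = 0,
                             confidence_noise_sd = 0,
                             seed = 1L) {
  cfg <- list(parameter = parameter, n_studies = n_studies,
              truth_mean = truth_mean, truth_sd = truth_sd,
              sigma_r = sigma_r, sigma_t = sigma_t,
              auto_bias = auto_bias, reader_biases = reader_biases,
              p_missing_human = p_missing_human,
              confidence_threshold = confidence_threshold,
              confidence_noise_sd = confidence_noise_sd,
              seed = seed)
  check_scalar <- function(x, field, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x < lower || x > upper) {
      stop("invalid generator config field: ", field, call. = FALSE)
    }
  }
  if (!is.character(cfg$parameter) || length(cfg$parameter) != 1L ||
      !nzchar(cfg$parameter)) {
    stop("invalid generator config field: parameter", call. = FALSE)
  }
  check_scalar(cfg$n_studies, "n_studies", lower = 1)
  check_scalar(cfg$truth_mean, "truth_mean")
  check_scalar(cfg$truth_sd, "truth_sd", lower = 0)
  check_scalar(cfg$sigma_r, "sigma_r", lower = 0)
  check_scalar(cfg$sigma_t, "sigma_t", lower = 0)
  check_scalar(cfg$auto_bias, "auto_bias")
  if (!is.numeric(cfg$reader_biases) || length(cfg$reader_biases) != 3L ||
      any(!is.finite(cfg$reader_biases))) {
    stop("invalid generator config field: reader_biases", call. = FALSE)
  }
  check_scalar(cfg$p_missing_human, "p_missing_human", 0, 1)
  check_scalar(cfg$confidence_threshold, "confidence_threshold", 0, 1)
  check_scalar(cfg$confidence_noise_sd, "confidence_noise_sd", lower = 0)
  check_scalar(cfg$seed, "seed")
  cfg$n_studies <- as.integer(cfg$n_studies)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "generator_config")
}

as_generator_config <- function(x) {
  if (inherits(x, "generator_config")) return(x)
  do.call(generator_config, as.list(x))
}

#' Generate one parameter's synthetic multi-reader dataset
#'
#' @param config A [generator_config()].
#' @param study_ids Optional character vector of study identifiers of
#'   length `n_studies`; defaults to `S0001`, `S0002`, ...
#' @return A list with `table` (long-format measurement tibble) and
#'   `audit` (seed, counts of emitted human triples, automated reads and
#'   complete quadruples, and the realized yield = quadruples/triples).
#' @export
generate_dataset <- function(config, study_ids = NULL) {
  cfg <- as_generator_config(config)
  n <- cfg$n_studies
  if (is.null(study_ids)) {
    study_ids <- sprintf("S%04d", seq_len(n))
  }
  stopifnot(length(study_ids) == n, !anyDuplicated(study_ids))

  sim <- with_rng(cfg$seed, {
    mu <- rnorm(n, cfg$truth_mean, cfg$truth_sd)
    e <- matrix(rnorm(3L * n, 0, cfg$sigma_r), nrow = n, ncol = 3L)
    u <- rnorm(n, 0, cfg$sigma_t)
    z <- if (cfg$sigma_t > 0) abs(u) / cfg$sigma_t else rep(0, n)
    conf <- 1 - pnorm(z)
    if (cfg$confidence_noise_sd > 0) {
      conf <- conf + rnorm(n, 0, cfg$confidence_noise_sd)
    }
    conf <- pmin(pmax(conf, 0), 1)
    human_kept <- matrix(runif(3L * n) >= cfg$p_missing_human,
                         nrow = n, ncol = 3L)
    list(mu = mu, e = e, u = u, conf = conf, human_kept = human_kept)
  })

  human <- sim$mu + rep(cfg$reader_biases, each = n) + sim$e
  auto <- sim$mu + cfg$auto_bias + sim$u
  auto_kept <- sim$conf >= cfg$confidence_threshold

  rows <- list()
  for (j in 1:3) {
    keep <- sim$human_kept[, j]
    rows[[j]] <- tibble::tibble(
      study_id = study_ids[keep], parameter = cfg$parameter,
      reader = HUMAN_READERS[j], value = human[keep, j]
    )
  }
  rows[[4L]] <- tibble::tibble(
    study_id = study_ids[auto_kept], parameter = cfg$parameter,
    reader = "AUTO", value = auto[auto_kept]
  )
  table <- dplyr::arrange(dplyr::bind_rows(rows),
                          .data$parameter, .data$study_id, .data$reader)

  triple <- rowSums(sim$human_kept) == 3L
  n_triples <- sum(triple)
  n_quads <- sum(triple & auto_kept)
  audit <- tibble::tibble(
    parameter = cfg$parameter, seed = cfg$seed, n_studies = n,
    n_triples = n_triples, n_auto = sum(auto_kept), n_quads = n_quads,
    realized_yield = if (n_triples > 0) n_quads / n_triples else NA_real_
  )
  list(table = table, audit = audit)
}

#' Generate a multi-parameter study suite
#'
#' Unions per-parameter generator outputs over one shared study-id
#' universe sized by the largest `n_studies`.  Per-parameter RNG
#' sub-streams are derived deterministically from each config's seed, so
#' the suite is reproducible as a whole.
#'
#' @param configs List of [generator_config()]s with distinct parameter
#'   names.
#' @return A list with `table` (combined measurement tibble) and `audit`
#'   (one row per parameter).
#' @export
generate_study_suite <- function(configs) {
  if (length(configs) == 0L) {
    return(list(
      table = tibble::tibble(study_id = character(), parameter = character(),
                             reader = character(), value = double()),
      audit = tibble::tibble()
    ))
  }
  configs <- lapply(configs, as_generator_config)
  pars <- vapply(configs, function(cfg) cfg$parameter, character(1))
  if (anyDuplicated(pars)) {
    stop("duplicate parameter names in study suite: ",
         paste(unique(pars[duplicated(pars)]), collapse = ", "),
         call. = FALSE)
  }
  n_max <- max(vapply(configs, function(cfg) cfg$n_studies, integer(1)))
  ids <- sprintf("S%04d", seq_len(n_max))
  out <- lapply(seq_along(configs), function(k) {
    cfg <- configs[[k]]
    cfg$seed <- derive_seed(cfg$seed, k)
    generate_dataset(cfg, study_ids = ids[seq_len(cfg$n_studies)])
  })
  list(
    table = dplyr::bind_rows(lapply(out, `[[`, "table")),
    audit = dplyr::bind_rows(lapply(out, `[[`, "audit"))
  )
}

#' Default 23-parameter study-suite configuration
#'
#' One [generator_config()] per catalogue parameter, emulating a
#' 600-study core-lab export: truth distributions at clinically typical
#' magnitudes for a heart-failure-enriched cohort, human reader error
#' SDs at the scale of published inter-sonographer residual spread, the
#' automated error variance set to `gamma` times the human variance, and
#' per-parameter confidence gates and human-read dropout calibrated so
#' expected triple counts and yields match a published core-lab
#' validation (see [corelab_yield_counts()]).
#'
#' @param n_studies Studies per parameter.
#' @param gamma Automated-to-human error variance ratio
#'   \eqn{\sigma_T^2/\sigma_R^2}.
#' @param seed Base seed for the suite.
#' @param confidence_noise_sd Confidence-score noise; 0 keeps the gate
#'   strictly MNAR.
#' @param calibrate_missingness If `TRUE` (default), set each
#'   parameter's confidence threshold and human dropout from the
#'   core-lab counts; if `FALSE`, no read is ever missing.
#' @return A named list of `generator_config`s.
#' @export
default_suite_configs <- function(n_studies = 600L, gamma = 0.8, seed = 1L,
                                  confidence_noise_sd = 0,
                                  calibrate_missingness = TRUE) {
  ## truth_mean/truth_sd: typical HFrEF-cohort magnitudes per parameter;
  ## sigma_r: at the scale of the published human-reader residual RMSE.
  spec <- tibble::tribble(
    ~parameter,          ~truth_mean, ~truth_sd, ~sigma_r,
    "IVSd",                   10,    2.0,   1.15,
    "LVIDd",                  58,    9.0,   2.97,
    "LVIDs",                  48,   10.0,   3.41,
    "LVPWd",                  10,    2.0,   1.09,
    "LVEDV MOD biplane",     180,   60.0,  25.09,
    "LVESV MOD biplane",     120,   55.0,  19.87,
    "LVEF MOD biplane",       35,   12.0,   6.69,
    "LAESV MOD biplane",      70,   25.0,  10.74,
    "RA area A4C",            18,    5.0,   1.80,
    "RVIDd",                  38,    7.0,   4.62,
    "LVSV MOD biplane",       55,   15.0,  11.74,
    "MV-Adur",               140,   30.0,  30.15,
    "MV-E",                   75,   25.0,   5.22,
    "MV-A",                   65,   25.0,   4.61,
    "DecT",                  200,   55.0,  34.04,
    "e' lateral",              8,    3.0,   1.05,
    "e' septal",               6,    2.0,   0.81,
    "E/e' mean",              12,    5.0,   1.78,
    "a' lateral",              8,    3.0,   0.84,
    "a' septal",               7,    2.5,   0.69,
    "s' lateral",              7,    2.0,   0.55,
    "s' septal",               6,    1.8,   0.43,
    "TR Vmax",               2.6,    0.5,   0.17
  )
  counts <- corelab_yield_counts()
  spec <- dplyr::left_join(spec, counts, by = "parameter")
  configs <- lapply(seq_len(nrow(spec)), function(k) {
    row <- spec[k, ]
    if (calibrate_missingness) {
      ## expected triples = n * (1 - p_miss)^3; expected yield = 1 - 2*tau
      p_miss <- 1 - (row$n_triples / 602)^(1 / 3)
      tau <- (1 - row$n_quads / row$n_triples) / 2
    } else {
      p_miss <- 0
      tau <- 0
    }
    generator_config(
      parameter = row$parameter, n_studies = n_studies,
      truth_mean = row$truth_mean, truth_sd = row$truth_sd,
      sigma_r = row$sigma_r, sigma_t = sqrt(gamma) * row$sigma_r,
      p_missing_human = p_miss, confidence_threshold = tau,
      confidence_noise_sd = confidence_noise_sd, seed = seed
    )
  })
  stats::setNames(configs, spec$parameter)
}
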