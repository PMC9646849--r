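#' Run the full interchangeability validation
#'
#' End-to-end orchestration: per-parameter IEC non-inferiority tests
#' (forest-plot data), the yield table, agreement reports for the
#' all-reader and human-only reader sets, and relative-absolute-
#' difference box summaries, with a provenance block.  Parameters with
#' fewer than 2 complete quadruples are marked `insufficient data` and
#' the run continues.  Given the same inputs and seed the bundle is
#' identical, byte for byte, when written.
#'
#' @param table A validated measurement table, or `NULL` to generate
#'   one from `configs`.
#' @param configs Optional list of [generator_config()]s used when
#'   `table` is `NULL` (e.g. [default_suite_configs()]).
#' @param parameters Parameters to analyse; default all present.
#' @param n_boot Bootstrap replicates per parameter.
#' @param seed Seed for all stochastic steps.
#' @param margin Non-inferiority margin.
#' @param cp_delta Single tolerance, or named numeric vector per
#'   parameter, for the coverage probability; `NA` is reported when
#'   absent.
#' @param out_dir Optional directory; when given, writes
#'   `iec_results.csv`, `yield.csv`, `agreement.csv`, `rad_summary.csv`
#'   and `bundle.json`.
#' @return A `validation_bundle` list: `iec_results`, `yield`,
#'   `agreement`, `rad_summary`, `insufficient`, `audit` (generator
#'   audit, when generated), `provenance`.
#' @export
run_validation <- function(table = NULL, configs = NULL, parameters = NULL,
                           n_boot = 10000L, seed = 1L, margin = 0.25,
                           cp_delta = NULL, out_dir = NULL) {
  audit <- NULL
  if (is.null(table)) {
    if (is.null(configs)) {
      stop("supply either a measurement table or generator configs",
           call. = FALSE)
    }
    suite <- generate_study_suite(configs)
    table <- suite$table
    audit <- suite$audit
  } else {
    table <- validate_measurements(table, catalogue = NULL)
  }
  if (is.null(parameters)) parameters <- sort(unique(table$parameter))

  delta_for <- function(p) {
    if (is.null(cp_delta)) return(NULL)
    if (length(cp_delta) == 1L && is.null(names(cp_delta))) {
      return(unname(cp_delta))
    }
    if (p %in% names(cp_delta)) return(unname(cp_delta[[p]])) else NULL
  }

  iec_rows <- list(); agr_rows <- list(); rad_rows <- list()
  insufficient <- character()
  for (k in seq_along(parameters)) {
    p <- parameters[k]
    quads <- complete_quadruples(table, p)
    if (nrow(quads) < 2L) {
      insufficient <- c(insufficient, p)
      next
    }
    res <- bootstrap_iec(quads, n_boot = n_boot,
                         seed = derive_seed(seed, k), margin = margin,
                         parameter = p)
    iec_rows[[p]] <- tibble::as_tibble(unclass(res))
    agr_rows[[p]] <- dplyr::bind_rows(
      agreement_report(table, p, c("R1", "R2", "R3", "AUTO"),
                       cp_delta = delta_for(p)),
      agreement_report(table, p, c("R1", "R2", "R3"),
                       cp_delta = delta_for(p))
    )
    rad <- relative_absolute_differences(table, p)
    rad_rows[[p]] <- dplyr::mutate(rad$summary, parameter = p, .before = 1)
  }

  bundle <- structure(list(
    iec_results = dplyr::bind_rows(iec_rows),
    yield = yield_table(table),
    agreement = dplyr::bind_rows(agr_rows),
    rad_summary = dplyr::bind_rows(rad_rows),
    insufficient = insufficient,
    audit = audit,
    provenance = list(
      package = "iecval",
      version = as.character(utils::packageVersion("iecval")),
      seed = as.integer(seed), n_boot = as.integer(n_boot),
      margin = margin,
      config_hash = rlang::hash(list(parameters, n_boot, seed, margin,
                                     cp_delta))
    )
  ), class = "validation_bundle")

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$iec_results, file.path(out_dir, "iec_results.csv"))
  readr::write_csv(bundle$yield, file.path(out_dir, "yield.csv"))
  readr::write_csv(bundle$agreement, file.path(out_dir, "agreement.csv"))
  readr::write_csv(bundle$rad_summary, file.path(out_dir, "rad_summary.csv"))
  jsonlite::write_json(unclass(bundle), file.path(out_dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.validation_bundle <- function(x, ...) {
  cat("Interchangeability validation bundle\n")
  cat(sprintf("  %d parameter(s) analysed, %d insufficient\n",
              nrow(x$iec_results), length(x$insufficient)))
  if (nrow(x$iec_results)) {
    cat(sprintf("  IEC range: %.3f to %.3f; %d/%d non-inferior at margin %.2f\n",
                min(x$iec_results$iec), max(x$iec_results$iec),
                sum(x$iec_results$noninferior), nrow(x$iec_results),
                x$provenance$margin))
  }
  cat(sprintf("  mean yield: %.3f (seed %d)\n",
              mean(x$yield$proportion, na.rm = TRUE), x$provenance$seed))
  invisible(x)
}

#' Confidence-threshold sensitivity comparison
#'
#' Regenerates the same synthetic suite (same seeds) under a strict and
#' a relaxed confidence gate and reports yield and IEC at both: with
#' the MNAR gate, relaxing the threshold admits the automated reads
#' with the largest errors, so yield rises while the IEC moves upward
#' (towards worse agreement) on average.
#'
#' @param configs List of [generator_config()]s (the strict thresholds
#'   in the configs are ignored; both `tau_strict` and `tau_relaxed`
#'   are applied to every parameter).
#' @param tau_strict,tau_relaxed Confidence thresholds with
#'   `tau_relaxed <= tau_strict`.
#' @param n_boot Bootstrap replicates per parameter and threshold.
#' @param seed Seed shared by both arms.
#' @param margin Non-inferiority margin.
#' @return A tibble with one row per parameter and threshold arm:
#'   `parameter`, `arm`, `tau`, `n_triples`, `n_quads`, `yield`, `n`,
#'   `iec`, `sd_boot`, `upper95`, `noninferior`.
#' @export
sensitivity_thresholds <- function(configs, tau_strict, tau_relaxed,
                                   n_boot = 2000L, seed = 1L,
                                   margin = 0.25) {
  if (tau_relaxed > tau_strict) {
    stop("tau_relaxed must not exceed tau_strict (labels swapped?)",
         call. = FALSE)
  }
  run_arm <- function(tau, arm) {
    cfgs <- lapply(configs, function(cfg) {
      cfg <- as_generator_config(cfg)
      cfg$confidence_threshold <- tau
      cfg
    })
    suite <- generate_study_suite(cfgs)
    rows <- lapply(seq_along(cfgs), function(k) {
      p <- cfgs[[k]]$parameter
      quads <- complete_quadruples(suite$table, p)
      triples <- human_triples(suite$table, p)
      base <- tibble::tibble(
        parameter = p, arm = arm, tau = tau,
        n_triples = nrow(triples), n_quads = nrow(quads),
        yield = if (nrow(triples)) nrow(quads) / nrow(triples) else NA_real_
      )
      if (nrow(quads) < 2L) {
        return(dplyr::mutate(base, n = nrow(quads), iec = NA_real_,
                             sd_boot = NA_real_, upper95 = NA_real_,
                             noninferior = NA))
      }
      res <- bootstrap_iec(quads, n_boot = n_boot,
                           seed = derive_seed(seed, k), margin = margin,
                           parameter = p)
      dplyr::mutate(base, n = res$n, iec = res$iec, sd_boot = res$sd_boot,
                    upper95 = res$upper95, noninferior = res$noninferior)
    })
    dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(run_arm(tau_strict, "strict"),
                   run_arm(tau_relaxed, "relaxed"))
}
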