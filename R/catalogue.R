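#' Default echocardiographic parameter catalogue
#'
#' The 23 standard echocardiographic parameters used in core-lab
#' interchangeability validation, with the units they are conventionally
#' reported in (mm, ml, %, cm2, cm/s, m/s, ms, or unitless for the E/e'
#' ratio).  Statistics in this package are unit-agnostic; the catalogue
#' exists for validation, labelling and as the default scope of the
#' synthetic study suite.
#'
#' @param extra Optional tibble of additional entries with columns
#'   `parameter`, `units`, and optionally `range_low`, `range_high`.
#' @return A tibble with columns `parameter`, `units`, `range_low`,
#'   `range_high` (plausible physiologic range, `NA` when not stated).
#' @export
#' @examples
#' parameter_catalogue()
parameter_catalogue <- function(extra = NULL) {
  cat23 <- tibble::tribble(
    ~parameter,          ~units,   ~range_low, ~range_high,
    "IVSd",              "mm",          2,   30,
    "LVIDd",             "mm",         20,  100,
    "LVIDs",             "mm",         10,  100,
    "LVPWd",             "mm",          2,   30,
    "LVEDV MOD biplane", "ml",         20,  700,
    "LVESV MOD biplane", "ml",         10,  600,
    "LVEF MOD biplane",  "%",           5,   90,
    "LAESV MOD biplane", "ml",          5,  400,
    "RA area A4C",       "cm2",         3,   80,
    "RVIDd",             "mm",         10,   80,
    "LVSV MOD biplane",  "ml",          5,  250,
    "MV-Adur",           "ms",         40,  400,
    "MV-E",              "cm/s",       10,  250,
    "MV-A",              "cm/s",       10,  250,
    "DecT",              "ms",         50,  600,
    "e' lateral",        "cm/s",        1,   40,
    "e' septal",         "cm/s",        1,   40,
    "E/e' mean",         "",            1,   60,
    "a' lateral",        "cm/s",        1,   40,
    "a' septal",         "cm/s",        1,   40,
    "s' lateral",        "cm/s",        1,   40,
    "s' septal",         "cm/s",        1,   40,
    "TR Vmax",           "m/s",         1,    7
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    stopifnot(all(c("parameter", "units") %in% names(extra)))
    if (!"range_low" %in% names(extra)) extra$range_low <- NA_real_
    if (!"range_high" %in% names(extra)) extra$range_high <- NA_real_
    cat23 <- dplyr::bind_rows(cat23, extra[names(cat23)])
  }
  if (anyDuplicated(cat23$parameter)) {
    stop("parameter catalogue names must be unique", call. = FALSE)
  }
  cat23
}

#' Published core-lab yield counts
#'
#' Per-parameter read counts from a published core-laboratory validation
#' of an automated echocardiographic workflow against three expert
#' sonographers: `n_triples` is the number of studies with all three
#' human reads and `n_quads` the subset that also received an automated
#' read.  These counts are the canonical worked example for the yield
#' statistics ([yield_proportion()], [yield_ci()], [average_yield()]).
#'
#' @return A tibble with columns `parameter`, `n_triples`, `n_quads`.
#' @export
#' @examples
#' counts <- corelab_yield_counts()
#' mean(counts$n_quads / counts$n_triples)
corelab_yield_counts <- function() {
  path <- system.file("extdata", "corelab_yield_counts.csv",
                      package = "iecval", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    parameter = readr::col_character(),
    n_triples = readr::col_integer(),
    n_quads   = readr::col_integer()
  ))
}
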