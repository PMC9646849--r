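#' Validate a long-format measurement table
#'
#' A measurement table holds one row per (study, parameter, reader)
#' triple, readers being the three human experts `R1`, `R2`, `R3` and
#' the automated source `AUTO`.  Missingness is represented by the
#' absence of a row, never by a sentinel value.
#'
#' @param table A data frame with columns `study_id`, `parameter`,
#'   `reader`, `value`.
#' @param catalogue Parameter catalogue (see [parameter_catalogue()]);
#'   set to `NULL` to skip the parameter-name check.
#' @return The validated table as a tibble, with `study_id`,
#'   `parameter`, `reader` as character and `value` as double, sorted by
#'   (parameter, study_id, reader) so row order of the input never
#'   affects downstream results.
#' @export
validate_measurements <- function(table, catalogue = parameter_catalogue()) {
  table <- tibble::as_tibble(table)
  required <- c("study_id", "parameter", "reader", "value")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  table <- dplyr::mutate(
    table[required],
    study_id  = as.character(.data$study_id),
    parameter = as.character(.data$parameter),
    reader    = as.character(.data$reader)
  )
  bad_reader <- setdiff(unique(table$reader), READER_LABELS)
  if (length(bad_reader)) {
    stop("unknown reader label(s): ", paste(bad_reader, collapse = ", "),
         "; allowed: ", paste(READER_LABELS, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(table$value)) {
    bad_row <- which(is.na(suppressWarnings(as.numeric(table$value))))
    stop("non-numeric value(s) at row(s): ",
         paste(head(bad_row, 5L), collapse = ", "), call. = FALSE)
  }
  table$value <- as.double(table$value)
  if (any(!is.finite(table$value))) {
    bad_row <- which(!is.finite(table$value))
    stop("non-finite value(s) at row(s): ",
         paste(head(bad_row, 5L), collapse = ", "),
         " (missingness must be an absent record, not NA/Inf)",
         call. = FALSE)
  }
  key <- paste(table$study_id, table$parameter, table$reader, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate record for (study_id, parameter, reader) = (",
         gsub("\r", ", ", dup, fixed = TRUE), ")", call. = FALSE)
  }
  if (!is.null(catalogue)) {
    unknown <- setdiff(unique(table$parameter), catalogue$parameter)
    if (length(unknown)) {
      stop("parameter(s) not in catalogue: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  dplyr::arrange(table, .data$parameter, .data$study_id, .data$reader)
}

#' Read a multi-reader measurement table from CSV
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param layout `"long"` (columns `study_id,parameter,reader,value`) or
#'   `"wide"` (columns `study_id,parameter,R1,R2,R3,AUTO`, blank cells
#'   meaning the read is missing).
#' @inheritParams validate_measurements
#' @return A validated long-format measurement tibble.
#' @export
read_measurements <- function(path, layout = c("long", "wide"),
                              catalogue = parameter_catalogue()) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (layout == "long") {
    raw <- readr::read_csv(path, col_types = readr::cols(
      study_id = readr::col_character(),
      parameter = readr::col_character(),
      reader = readr::col_character(),
      value = readr::col_character()
    ))
    suppressWarnings(num <- as.numeric(raw$value))
    if (any(is.na(num))) {
      stop("non-numeric value at data row(s): ",
           paste(head(which(is.na(num)), 5L), collapse = ", "),
           call. = FALSE)
    }
    raw$value <- num
  } else {
    wide <- readr::read_csv(path,
                            col_types = readr::cols(.default = readr::col_character()))
    missing_cols <- setdiff(c("study_id", "parameter", READER_LABELS),
                            names(wide))
    if (length(missing_cols)) {
      stop("wide layout lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (lab in READER_LABELS) {
      raw_col <- wide[[lab]]
      num <- suppressWarnings(as.numeric(raw_col))
      bad <- !is.na(raw_col) & nzchar(raw_col) & is.na(num)
      if (any(bad)) {
        stop("non-numeric ", lab, " value at data row(s): ",
             paste(head(which(bad), 5L), collapse = ", "), call. = FALSE)
      }
      wide[[lab]] <- num
    }
    raw <- tidyr::pivot_longer(wide, cols = dplyr::all_of(READER_LABELS),
                               names_to = "reader", values_to = "value")
    raw <- dplyr::filter(raw, !is.na(.data$value))
  }
  validate_measurements(raw, catalogue = catalogue)
}

#' Write a measurement table to CSV
#'
#' Round-trips exactly through [read_measurements()]: values are written
#' at full double precision.
#'
#' @param table A validated measurement table.
#' @param path Output CSV path.
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  table <- validate_measurements(table, catalogue = NULL)
  if (layout == "wide") {
    table <- tidyr::pivot_wider(table, names_from = "reader",
                                values_from = "value")
    for (lab in setdiff(READER_LABELS, names(table))) table[[lab]] <- NA_real_
    table <- table[c("study_id", "parameter", READER_LABELS)]
  }
  readr::write_csv(table, path, na = "")
  invisible(path)
}

wide_reads <- function(table, parameter) {
  stopifnot(is.character(parameter), length(parameter) == 1L)
  if (!parameter %in% table$parameter &&
      !parameter %in% parameter_catalogue()$parameter) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  sub <- dplyr::filter(table, .data$parameter == !!parameter)
  wide <- tidyr::pivot_wider(sub[c("study_id", "reader", "value")],
                             names_from = "reader", values_from = "value")
  for (lab in setdiff(READER_LABELS, names(wide))) wide[[lab]] <- NA_real_
  dplyr::arrange(wide[c("study_id", READER_LABELS)], .data$study_id)
}

#' Studies with a complete reader quadruple for one parameter
#'
#' Returns the studies holding all three human reads and the automated
#' read — the analysis set of the primary endpoint.  The number of rows
#' equals the yield numerator for that parameter.
#'
#' @param table A validated measurement table.
#' @param parameter Parameter name.
#' @return A tibble with columns `study_id`, `R1`, `R2`, `R3`, `AUTO`,
#'   ordered by `study_id`.
#' @export
complete_quadruples <- function(table, parameter) {
  wide <- wide_reads(table, parameter)
  dplyr::filter(
    wide,
    !is.na(.data$R1), !is.na(.data$R2), !is.na(.data$R3), !is.na(.data$AUTO)
  )
}

#' Studies with all three human reads for one parameter
#'
#' Presence of an automated read is irrelevant; the number of rows
#' equals the yield denominator for that parameter.
#'
#' @inheritParams complete_quadruples
#' @return A tibble with columns `study_id`, `R1`, `R2`, `R3`, ordered
#'   by `study_id`.
#' @export
human_triples <- function(table, parameter) {
  wide <- wide_reads(table, parameter)
  out <- dplyr::filter(wide, !is.na(.data$R1), !is.na(.data$R2),
                       !is.na(.data$R3))
  out[c("study_id", HUMAN_READERS)]
}
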