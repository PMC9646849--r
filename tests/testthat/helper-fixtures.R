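# Build a long measurement table from a wide spec: a tibble/data.frame
# with columns study_id, parameter, R1, R2, R3, AUTO (NA = missing read).
make_table <- function(wide) {
  wide <- tibble::as_tibble(wide)
  long <- tidyr::pivot_longer(wide, cols = dplyr::any_of(c("R1", "R2", "R3", "AUTO")),
                              names_to = "reader", values_to = "value")
  long <- dplyr::filter(long, !is.na(value))
  validate_measurements(long, catalogue = NULL)
}

# Random complete quadruples for oracle comparisons.
random_quads <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    study_id = sprintf("S%03d", seq_len(n)),
    R1 = rnorm(n, 50, 10), R2 = rnorm(n, 50, 10), R3 = rnorm(n, 50, 10),
    AUTO = rnorm(n, 50, 10)
  )
}

quads_to_table <- function(quads, parameter = "LVEF MOD biplane") {
  make_table(dplyr::mutate(quads, parameter = parameter, .after = 1))
}
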