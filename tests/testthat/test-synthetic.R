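test_that("degenerate noise gives four identical reads per study", {
  cfg <- generator_config(n_studies = 10, sigma_r = 0, sigma_t = 0,
                          auto_bias = 0, seed = 5)
  tab <- generate_dataset(cfg)$table
  spread <- tapply(tab$value, tab$study_id, function(v) diff(range(v)))
  expect_true(all(spread == 0))
  expect_equal(nrow(tab), 40L)
})

test_that("the seed fully determines the table", {
  cfg <- generator_config(n_studies = 50, p_missing_human = 0.1,
                          confidence_threshold = 0.2,
                          confidence_noise_sd = 0.05, seed = 123)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$audit, b$audit)
  cfg$seed <- 124L
  expect_false(identical(generate_dataset(cfg)$table$value, a$table$value))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- rnorm(3)
  set.seed(77)
  invisible(generate_dataset(generator_config(n_studies = 5, seed = 1)))
  expect_identical(rnorm(3), before)
})

test_that("pooled automated-human difference variance matches sigma_t^2 + sigma_r^2", {
  cfg <- generator_config(n_studies = 600, sigma_r = 4, sigma_t = 4,
                          truth_sd = 12, seed = 2024)
  quads <- complete_quadruples(generate_dataset(cfg)$table, cfg$parameter)
  d <- c(quads$AUTO - quads$R1, quads$AUTO - quads$R2, quads$AUTO - quads$R3)
  # closed form: var(a - h) = sigma_t^2 + sigma_r^2 = 32; MC tolerance
  expect_equal(var(d), 32, tolerance = 0.1)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(generator_config(sigma_r = -1), "sigma_r")
  expect_error(generator_config(p_missing_human = 1.2), "p_missing_human")
  expect_error(generator_config(n_studies = 0), "n_studies")
  expect_error(generator_config(reader_biases = c(0, 0)), "reader_biases")
  expect_error(generator_config(confidence_threshold = -0.1),
               "confidence_threshold")
})

test_that("audit counts are consistent with the emitted table", {
  cfg <- generator_config(n_studies = 200, p_missing_human = 0.1,
                          confidence_threshold = 0.15, seed = 8)
  out <- generate_dataset(cfg)
  expect_equal(out$audit$n_triples, nrow(human_triples(out$table, cfg$parameter)))
  expect_equal(out$audit$n_quads, nrow(complete_quadruples(out$table, cfg$parameter)))
  expect_equal(out$audit$n_auto, sum(out$table$reader == "AUTO"))
  expect_equal(out$audit$realized_yield,
               out$audit$n_quads / out$audit$n_triples)
})

test_that("lowering the confidence threshold never lowers realized yield", {
  for (seed in c(1, 17, 300)) {
    base <- generator_config(n_studies = 300, confidence_noise_sd = 0.03,
                             seed = seed)
    taus <- c(0.4, 0.25, 0.1, 0)
    yields <- sapply(taus, function(tau) {
      cfg <- base; cfg$confidence_threshold <- tau
      generate_dataset(cfg)$audit$realized_yield
    })
    expect_true(all(diff(yields) >= 0))
    expect_equal(yields[length(yields)], 1)
  }
})

test_that("with a noiseless gate, suppressed automated reads have larger errors", {
  cfg <- generator_config(n_studies = 500, confidence_threshold = 0.2,
                          confidence_noise_sd = 0, truth_sd = 0,
                          truth_mean = 50, seed = 31)
  tab <- generate_dataset(cfg)$table
  open_cfg <- cfg; open_cfg$confidence_threshold <- 0
  all_auto <- dplyr::filter(generate_dataset(open_cfg)$table, reader == "AUTO")
  kept_ids <- dplyr::filter(tab, reader == "AUTO")$study_id
  err <- abs(all_auto$value - 50)
  kept <- all_auto$study_id %in% kept_ids
  expect_gt(mean(err[!kept]), mean(err[kept]))
  # deterministic gate: kept errors all below every suppressed error
  expect_lt(max(err[kept]), min(err[!kept]))
})

test_that("study suites share one study-id universe and reject duplicate parameters", {
  cfgs <- list(
    generator_config(parameter = "IVSd", n_studies = 10, seed = 1),
    generator_config(parameter = "LVIDd", n_studies = 10, seed = 1)
  )
  suite <- generate_study_suite(cfgs)
  expect_setequal(unique(suite$table$parameter), c("IVSd", "LVIDd"))
  expect_equal(length(unique(suite$table$study_id)), 10L)
  expect_error(generate_study_suite(cfgs[c(1, 1)]), "duplicate parameter")
  empty <- generate_study_suite(list())
  expect_equal(nrow(empty$table), 0L)
})

test_that("the default 23-parameter suite yields drop when thresholds tighten", {
  relaxed <- generate_study_suite(default_suite_configs(n_studies = 150, seed = 4))
  cfgs_strict <- lapply(default_suite_configs(n_studies = 150, seed = 4),
                        function(cfg) {
                          cfg$confidence_threshold <-
                            min(1, cfg$confidence_threshold + 0.1)
                          cfg
                        })
  strict <- generate_study_suite(cfgs_strict)
  expect_equal(nrow(relaxed$audit), 23L)
  expect_true(all(strict$audit$realized_yield <= relaxed$audit$realized_yield))
  expect_lt(mean(strict$audit$realized_yield),
            mean(relaxed$audit$realized_yield))
})
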