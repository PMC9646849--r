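test_that("ICC is 1 for perfect agreement and matches the ANOVA oracle", {
  perfect <- matrix(rep(1:5, 3), ncol = 3)
  expect_equal(icc(perfect), 1)

  grid <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3), c(4, 4, 5))
  expect_equal(icc(grid), anova_oracle(grid)$icc, tolerance = 1e-12)

  for (seed in 1:15) {
    set.seed(seed)
    m <- matrix(rnorm(60, 50, 8), ncol = 3) +
      matrix(rep(rnorm(3, 0, 2), each = 20), ncol = 3)
    expect_equal(icc(m), anova_oracle(m)$icc, tolerance = 1e-10)
  }
  expect_error(icc(matrix(3, nrow = 4, ncol = 3)), "zero")
})

test_that("MAD averages absolute pairwise reader differences", {
  expect_equal(mad_pairwise(matrix(c(10, 12, 14), nrow = 1)), 8 / 3)
  expect_equal(mad_pairwise(matrix(rep(4, 9), nrow = 3)), 0)
  two <- rbind(c(10, 12, 14), c(5, 5, 9))
  # six pair differences: (2,4,2) and (0,4,4)
  expect_equal(mad_pairwise(two), 8 / 3)
})

test_that("wCV is the root mean squared per-study CV, in percent, and scale-free", {
  expect_equal(wcv(matrix(c(9, 11), nrow = 1)), 100 * sqrt(2 / 100))
  expect_equal(wcv(matrix(rep(7, 6), nrow = 2)), 0)
  set.seed(2)
  m <- matrix(rnorm(45, 40, 5), ncol = 3)
  expect_equal(wcv(3 * m), wcv(m), tolerance = 1e-12)
  expect_error(wcv(matrix(c(-1, 1), nrow = 1)), "mean of zero")
})

test_that("two-way residual RMSE vanishes under additive structure and matches ANOVA", {
  additive <- outer(c(10, 20, 30, 40), rep(1, 3)) +
    outer(rep(1, 4), c(-1, 0, 2))
  expect_equal(rmse_twoway(additive), 0)
  expect_equal(rmse_twoway(matrix(5, 3, 3)), 0)

  m <- matrix(5, 3, 3); m[2, 3] <- 8
  expect_equal(rmse_twoway(m), anova_oracle(m)$rmse, tolerance = 1e-12)
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(rnorm(48), ncol = 4)
    expect_equal(rmse_twoway(m), anova_oracle(m)$rmse, tolerance = 1e-10)
  }
})

test_that("CCC matches its closed forms, the oracle, and Lin's inequality", {
  x <- c(3, 5, 7, 9, 12)
  expect_equal(ccc(x, x), 1)
  d <- 2; s2 <- mean((x - mean(x))^2)
  expect_equal(ccc(x, x + d), 2 * s2 / (2 * s2 + d^2))
  for (seed in 1:20) {
    set.seed(seed)
    a <- rnorm(10); b <- 0.8 * a + rnorm(10, 1, 0.5)
    expect_equal(ccc(a, b), ccc_oracle(a, b), tolerance = 1e-12)
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
  expect_error(ccc(rep(1, 5), rep(1, 5)), "constant")
})

test_that("Bland-Altman limits and coverage probability follow their definitions", {
  ba <- bland_altman(c(1, 2, 3) + 0.5, c(1, 2, 3))
  expect_equal(ba$center, 0.5)
  expect_equal(ba$halfwidth, 0)
  expect_equal(bland_altman(1:5, 1:5)$center, 0)
  ba3 <- bland_altman(c(0, 1, 2), c(1, 1, 1))
  expect_equal(ba3$halfwidth, 1.96 * 1)
  expect_equal(nrow(ba3$points), 3L)

  expect_equal(coverage_probability(1:4, 1:4, delta = 0.1), 1)
  expect_equal(coverage_probability(c(1, 3), c(0, 0), delta = 2), 0.5)
  expect_equal(coverage_probability(c(1, 3), c(0, 0), delta = 1e9), 1)
  expect_error(coverage_probability(1, 1, delta = 0), "positive")
})

test_that("about 95% of normal differences fall inside the limits of agreement", {
  set.seed(808)
  x <- rnorm(4000, 10, 2); y <- x + rnorm(4000, 0.3, 1.5)
  ba <- bland_altman(x, y)
  inside <- mean(abs((x - y) - ba$center) <= ba$halfwidth)
  expect_equal(inside, 0.95, tolerance = 0.01)
})

test_that("MAD and RMSE are translation-invariant and scale linearly; ICC/CCC/wCV scale-free", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- matrix(rnorm(36, 30, 4), ncol = 3)
    c_scale <- 2.5; d_shift <- 7
    m2 <- c_scale * m + d_shift
    expect_equal(mad_pairwise(m + d_shift), mad_pairwise(m), tolerance = 1e-12)
    expect_equal(rmse_twoway(m + d_shift), rmse_twoway(m), tolerance = 1e-12)
    expect_equal(mad_pairwise(c_scale * m), c_scale * mad_pairwise(m),
                 tolerance = 1e-12)
    expect_equal(rmse_twoway(c_scale * m), c_scale * rmse_twoway(m),
                 tolerance = 1e-12)
    expect_equal(icc(m2), icc(m), tolerance = 1e-10)
    expect_equal(ccc(m2[, 1], m2[, 2]), ccc(m[, 1], m[, 2]), tolerance = 1e-10)
  }
})

test_that("relative absolute differences use the pair mean and order by error variance", {
  one <- make_table(tibble::tibble(study_id = "S1", parameter = "MV-E",
                                   R1 = 10, R2 = 12.5, R3 = 10, AUTO = 10))
  rad <- relative_absolute_differences(one, "MV-E")
  expect_equal(sort(unique(round(rad$human_human, 4))), c(0, 0.2222))
  expect_true(0.2222 %in% round(rad$auto_human, 4))

  equal_auto <- make_table(tibble::tibble(
    study_id = c("S1", "S2"), parameter = "MV-E",
    R1 = c(10, 20), R2 = c(10, 20), R3 = c(10, 20), AUTO = c(10, 20)
  ))
  rad2 <- relative_absolute_differences(equal_auto, "MV-E")
  expect_true(all(rad2$auto_human == 0))

  # sigma_t < sigma_r forces smaller automated-human relative differences
  cfg <- generator_config(n_studies = 400, truth_mean = 60, truth_sd = 5,
                          sigma_r = 6, sigma_t = 2, seed = 21)
  tab <- generate_dataset(cfg)$table
  rad3 <- relative_absolute_differences(tab, cfg$parameter)
  expect_lt(median(rad3$auto_human), median(rad3$human_human))
  expect_equal(rad3$summary$comparison, c("human-human", "auto-human"))
})

test_that("the agreement report assembles the battery and respects the reader set", {
  perfect <- make_table(tibble::tibble(
    study_id = sprintf("S%d", 1:6), parameter = "LVEF MOD biplane",
    R1 = 10 * (1:6), R2 = 10 * (1:6), R3 = 10 * (1:6), AUTO = 10 * (1:6)
  ))
  rep4 <- agreement_report(perfect, "LVEF MOD biplane", cp_delta = 5)
  expect_equal(rep4$icc, 1)
  expect_equal(rep4$mad, 0)
  expect_equal(rep4$wcv, 0)
  expect_equal(rep4$rmse, 0)
  expect_equal(rep4$ccc, 1)
  expect_equal(c(rep4$loa_center, rep4$loa_halfwidth), c(0, 0))
  expect_equal(rep4$cp, 1)

  # humans-only report must not see AUTO
  skewed <- make_table(tibble::tibble(
    study_id = sprintf("S%d", 1:6), parameter = "LVEF MOD biplane",
    R1 = 10 * (1:6), R2 = 10 * (1:6), R3 = 10 * (1:6), AUTO = rnorm(6, 1000)
  ))
  rep3 <- agreement_report(skewed, "LVEF MOD biplane",
                           readers = c("R1", "R2", "R3"))
  expect_equal(rep3$icc, 1)
  expect_equal(rep3$mad, 0)
  expect_true(is.na(rep3$ccc))

  # exchangeable automated reader leaves the ICC essentially unchanged
  cfg <- generator_config(n_studies = 500, sigma_r = 5, sigma_t = 5, seed = 13)
  tab <- generate_dataset(cfg)$table
  icc4 <- agreement_report(tab, cfg$parameter)$icc
  icc3 <- agreement_report(tab, cfg$parameter, readers = c("R1", "R2", "R3"))$icc
  expect_equal(icc4, icc3, tolerance = 0.03)
})

test_that("adding a lower-variance automated reader decreases the expected MAD", {
  mads <- sapply(1:30, function(s) {
    cfg <- generator_config(n_studies = 200, sigma_r = 5, sigma_t = 2.5,
                            seed = 6000 + s)
    tab <- generate_dataset(cfg)$table
    c(all4 = mad_pairwise(readings_matrix(tab, cfg$parameter)),
      humans = mad_pairwise(readings_matrix(tab, cfg$parameter,
                                            c("R1", "R2", "R3"))))
  })
  expect_lt(mean(mads["all4", ]), mean(mads["humans", ]))
})
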