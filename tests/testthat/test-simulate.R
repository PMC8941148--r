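test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_dates = 0), "n_dates")
  expect_error(sim_config(date_sd = -1), "date_sd")
  expect_error(sim_config(true_ir_effect_respiration = -1.2), "effects")
  # noise so large that negative rates are likely -> unusable scenario
  expect_error(sim_config(date_sd = 0.2, residual_sd = 0.1), "unusable")
})

test_that("the same seed reproduces byte-identical tables", {
  a <- simulate_study(sim_config(n_dates = 4, seed = 77))
  b <- simulate_study(sim_config(n_dates = 4, seed = 77))
  expect_identical(a$titration_table, b$titration_table)
  expect_identical(a$scintillation_table, b$scintillation_table)
  expect_identical(a$gran_table, b$gran_table)
  expect_identical(a$count_table, b$count_table)
  c2 <- simulate_study(sim_config(n_dates = 4, seed = 78))
  expect_false(identical(a$titration_table$titrant_volume_l,
                         c2$titration_table$titrant_volume_l))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_activity(sim_config(n_dates = 2, seed = 9)))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free simulation carries the exact configured mean structure", {
  st <- simulate_activity(noise_free_config())
  o2 <- winkler_o2_table(st$titration_table, st$standardization_table)
  r <- bottle_rates(o2)
  ir <- r$value[r$analyte == "respiration" & r$treatment == "IR"]
  expect_equal(ir, rep(0.30 * (1 - 0.152), length(ir)), tolerance = 1e-9)
  trc <- tracer_rates(st$scintillation_table, st$truth$carbonate)
  for (an in c("glucose", "pyruvate", "leucine")) {
    truth <- st$truth$rates
    want <- truth$expected[truth$analyte == an & truth$treatment == "IR"][1]
    got <- trc$value[trc$analyte == an & trc$treatment == "IR"]
    expect_equal(got, rep(want, length(got)), tolerance = 1e-9)
  }
})

test_that("every (date, treatment) cell has the configured replicate count", {
  st <- simulate_activity(sim_config(n_dates = 5, replicates_per_treatment = 4,
                                     seed = 3))
  tab <- table(st$titration_table$date, st$titration_table$treatment)
  expect_true(all(tab == 4))
  mono <- st$scintillation_table[st$scintillation_table$substrate == "glucose" &
                                   st$scintillation_table$vial == "sample", ]
  expect_true(all(table(mono$date, mono$treatment) == 4))
})

test_that("simulated dark rates converge to the configured mean", {
  # >= 1e4 bottles: 120 dates x 28 replicates x 3 treatments >= needed
  cfg <- sim_config(n_dates = 120, replicates_per_treatment = 28, seed = 19)
  st <- simulate_activity(cfg)
  o2 <- winkler_o2_table(st$titration_table, st$standardization_table)
  r <- bottle_rates(o2)
  dark <- r$value[r$analyte == "respiration" & r$treatment == "dark"]
  expect_gte(length(dark), 3000)
  se <- sqrt(cfg$date_sd^2 / 120 + cfg$residual_sd^2 / length(dark))
  expect_lt(abs(mean(dark) - 0.30), 3 * se + 1e-3)
})

test_that("community counts covary with temperature and include a null covariate", {
  cfg <- sim_config(seed = 5)
  cm <- simulate_community(cfg, n_samples = 24)
  expect_equal(dim(cm$counts), c(24, 150))
  expect_equal(unname(rowSums(cm$counts)), rep(20000, 24))
  expect_named(cm$covariates, c("temperature", "aap", "null"))
  expect_equal(unname(cm$truth$effects["null"]), 0)
  expect_error(simulate_community(sim_config(
    community = list(n_asvs = 50, depth = 50, theta = 300,
                     effect_temperature = 0, effect_aap = 0))), "depth")
})

test_that("study tables round-trip losslessly through the CSV writers", {
  st <- simulate_study(sim_config(n_dates = 3, seed = 13))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  for (tb in c("titration_table", "standardization_table",
               "scintillation_table", "gran_table", "station_table",
               "covariate_table")) {
    got <- back[[tb]]; want <- st[[tb]]
    rownames(got) <- rownames(want) <- NULL
    attr(got, "provenance") <- NULL
    expect_equal(got, want, tolerance = 1e-15, label = tb)
  }
  expect_equal(unname(back$count_table), unname(st$count_table))
  # provenance headers present and skipped by the reader
  prov <- attr(read_table_csv(file.path(dir, "titration_table.csv")), "provenance")
  expect_true(any(grepl("seed", prov)))
})
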