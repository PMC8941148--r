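test_that("photoperiod matches solar-calculator benchmarks", {
  # equinox at the lake latitude: ~12 h (slightly above, -0.833 deg horizon)
  expect_lt(abs(photoperiod(as.Date("2018-03-20"), 48.944) - 12.0), 0.2)
  # equator: ~12.1 h year-round
  days <- as.Date("2018-01-01") + seq(0, 360, by = 30)
  eq <- photoperiod(days, 0)
  expect_true(all(abs(eq - 12.1) < 0.1))
  # solstice ordering
  expect_gt(photoperiod(as.Date("2018-06-21"), 48.944),
            photoperiod(as.Date("2018-12-21"), 48.944))
  expect_error(photoperiod(as.Date("2018-06-21"), 70), "polar")
})

test_that("daily rates weight the IR effect by the light time", {
  d <- daily_rates(0.2, 0.30, 0.27, 12)
  expect_equal(d$resp_ir_daily, 0.27 * 12 + 0.30 * 12)
  expect_equal(d$resp_ir_daily, 6.84)
  expect_equal(d$npp_daily, 2.4)
  expect_equal(d$resp_dark_daily, 7.2)
  # limits: no light -> IR equals dark; all light -> pure IR
  expect_equal(daily_rates(0.2, 0.3, 0.27, 0)$resp_ir_daily,
               daily_rates(0.2, 0.3, 0.27, 0)$resp_dark_daily)
  expect_equal(daily_rates(0.2, 0.3, 0.27, 24)$resp_ir_daily, 0.27 * 24)
  expect_error(daily_rates(0.2, 0.3, 0.27, 25), "light_hours")
})

make_days <- function(dates, npp, rd, ri, L = 12, temp = 18) {
  data.frame(date = as.Date(dates), npp_rate = npp, resp_dark = rd,
             resp_ir = ri, light_hours = L, water_temperature = temp)
}

test_that("seasonal integration: constant extension and trapezoid", {
  one <- make_days("2018-06-01", 0.1, 0.30, 0.30)
  cfg <- season_config(season_days = 180)
  integ <- integrate_season(one, cfg)
  expect_equal(integ$resp_dark, 7.2 * 180)
  # two days, daily values 6 and 10, 4 days apart, window exactly that span
  two <- make_days(c("2018-06-01", "2018-06-05"), 0, c(0.25, 10 / 24),
                   c(0.25, 10 / 24))
  integ2 <- integrate_season(two, season_config(season_days = 4))
  expect_equal(integ2$resp_dark, (6 + 10) / 2 * 4)
  # additivity over adjacent windows
  a <- integrate_season(two, season_config(season_days = 2))$resp_dark
  mid <- make_days(c("2018-06-03", "2018-06-05"), 0, c(8 / 24, 10 / 24),
                   c(8 / 24, 10 / 24))
  b <- integrate_season(mid, season_config(season_days = 2))$resp_dark
  expect_equal(a + b, integ2$resp_dark)
  # cold days are excluded from the window
  cold <- make_days(c("2018-04-01", "2018-06-01"), 0.1, c(9, 0.30), c(9, 0.30),
                    temp = c(5, 18))
  expect_equal(integrate_season(cold, cfg)$resp_dark, 7.2 * 180)
  expect_error(integrate_season(make_days("2018-06-01", .1, .3, .3, temp = 4), cfg),
               "temperature threshold")
})

test_that("lake upscaling follows the stated arithmetic and is linear", {
  cfg <- season_config()
  # 1296 umol/L over 5.8e8 L at RQ 1 and 44.01 g/mol
  expect_equal(lake_budget(1296, cfg), 1296e-6 * 44.01 * 5.8e8)
  expect_equal(lake_budget(0, cfg), 0)
  deep <- season_config(layer_depth = 1.0)
  expect_equal(lake_budget(1296, deep), 2 * lake_budget(1296, cfg))
  rq2 <- season_config(respiratory_quotient = 2)
  expect_equal(lake_budget(1296, rq2), 2 * lake_budget(1296, cfg))
})

test_that("dark-minus-IR budget difference: worked value, cancellation, sign", {
  # constant L = 12 h, rate gap 0.03 umol O2/L/h, 180 days, default lake
  days <- make_days(c("2018-05-01", "2018-08-01"), 0.2, 0.30, 0.27)
  b <- budget_difference(days, season_config())
  expect_equal(b$difference_dark_minus_ir_g, 0.03 * 12 * 180 * 1e-6 * 44.01 * 5.8e8,
               tolerance = 1e-12)
  expect_equal(b$difference_dark_minus_ir_g, 1.654e6, tolerance = 1e-3)
  # NPP cancels exactly in the difference
  days2 <- days; days2$npp_rate <- c(5, 9)
  b2 <- budget_difference(days2, season_config())
  expect_equal(b2$difference_dark_minus_ir_g, b$difference_dark_minus_ir_g)
  expect_equal(b$excess_dark_g - b$excess_ir_g, b$difference_dark_minus_ir_g)
  # equal scenarios -> zero difference; resp_ir <= resp_dark -> non-negative
  same <- make_days(c("2018-05-01", "2018-08-01"), 0.2, 0.30, 0.30)
  expect_equal(budget_difference(same, season_config())$difference_dark_minus_ir_g, 0)
  expect_gte(b$difference_dark_minus_ir_g, 0)
})
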