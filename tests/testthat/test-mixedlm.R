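make_lmm_data <- function(J = 8, r = 3, mu = 0.3, effect = -0.15,
                          date_sd = 0.08, resid_sd = 0.02, seed = 1) {
  withr::with_seed(seed, {
    date <- factor(rep(seq_len(J), each = 2 * r))
    treatment <- factor(rep(rep(c("dark", "IR"), each = r), J),
                        levels = c("dark", "IR"))
    b <- rnorm(J, 0, date_sd)
    y <- (mu + b[as.integer(date)]) * ifelse(treatment == "IR", 1 + effect, 1) +
      rnorm(J * 2 * r, 0, resid_sd)
    data.frame(value = y, treatment = treatment, date = date)
  })
}

test_that("with no between-date variance the fit reduces to OLS", {
  d <- make_lmm_data(J = 6, date_sd = 0, seed = 4)
  f <- fit_lmm(value ~ treatment, d)
  ols <- coef(lm(value ~ treatment, d))
  expect_equal(f$coefficients$estimate, unname(ols), tolerance = 1e-6)
})

test_that("profiled ML attains the brute-force likelihood maximum", {
  # tiny fixed dataset: 2 dates x 2 treatments x 2 reps
  d <- data.frame(
    value = c(0.31, 0.29, 0.26, 0.25, 0.35, 0.33, 0.30, 0.28),
    treatment = factor(rep(rep(c("dark", "IR"), each = 2), 2),
                       levels = c("dark", "IR")),
    date = factor(rep(1:2, each = 4)))
  f <- fit_lmm(value ~ treatment, d)

  # independent brute force: direct multivariate-normal likelihood over a
  # (sigma_d^2, sigma^2) grid, maximizing beta by GLS at each grid point
  X <- model.matrix(~treatment, d)
  loglik_at <- function(sd2, s2) {
    V <- diag(s2, 8) + sd2 * outer(d$date, d$date, "==")
    Vi <- solve(V)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$value)
    r <- d$value - X %*% beta
    -0.5 * (8 * log(2 * pi) + determinant(V)$modulus[1] +
              t(r) %*% Vi %*% r)[1]
  }
  grid <- expand.grid(sd2 = exp(seq(log(1e-8), log(0.1), length.out = 60)),
                      s2 = exp(seq(log(1e-6), log(0.1), length.out = 60)))
  lls <- mapply(loglik_at, grid$sd2, grid$s2)
  expect_gte(f$loglik + 1e-7, max(lls))
  expect_equal(f$loglik, loglik_at(f$sigma_d2, f$sigma2), tolerance = 1e-9)
  expect_equal(f$loglik, max(lls), tolerance = 1e-4)
})

test_that("fit agrees with an established mixed-model implementation", {
  d <- make_lmm_data(J = 10, seed = 9)
  f <- fit_lmm(value ~ treatment, d)
  m <- nlme::lme(value ~ treatment, random = ~ 1 | date, data = d,
                 method = "ML")
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(f$coefficients$estimate, unname(nlme::fixef(m)),
               tolerance = 1e-6)
  expect_equal(sqrt(c(f$sigma_d2, f$sigma2)),
               unname(as.numeric(nlme::VarCorr(m)[, 2])), tolerance = 1e-5)
  # REML variant
  fr <- fit_lmm(value ~ treatment, d, reml = TRUE)
  mr <- nlme::lme(value ~ treatment, random = ~ 1 | date, data = d,
                  method = "REML")
  expect_equal(sqrt(c(fr$sigma_d2, fr$sigma2)),
               unname(as.numeric(nlme::VarCorr(mr)[, 2])), tolerance = 1e-4)
})

test_that("fit is equivariant under affine rescaling of the response", {
  d <- make_lmm_data(seed = 12)
  f1 <- fit_lmm(value ~ treatment, d)
  d2 <- d; d2$value <- 10 * d$value
  f2 <- fit_lmm(value ~ treatment, d2)
  expect_equal(f2$coefficients$estimate, 10 * f1$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(f2$sigma2, 100 * f1$sigma2, tolerance = 1e-5)
  expect_equal(f2$sigma_d2, 100 * f1$sigma_d2, tolerance = 1e-4)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- make_lmm_data(seed = 3)
  d$x <- 1
  expect_error(fit_lmm(value ~ treatment + x, d), "singular")
  one <- data.frame(value = rnorm(6), date = factor(1:6),
                    treatment = factor(rep(c("dark", "IR"), 3)))
  expect_error(fit_lmm(value ~ treatment, one), "confounded|identifiable")
})

test_that("likelihood-ratio ANOVA: chi-squared reference and edge cases", {
  d <- make_lmm_data(seed = 5)
  full <- fit_lmm(value ~ treatment, d)
  null <- fit_lmm(value ~ 1, d)
  t1 <- lrt_anova(full, null)
  expect_equal(t1$df, 1)
  expect_equal(t1$statistic, 2 * (full$loglik - null$loglik))
  expect_equal(t1$p_value, pchisq(t1$statistic, 1, lower.tail = FALSE))
  # 3.84 on 1 df is the 5% point
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  t0 <- lrt_anova(full, full)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_error(lrt_anova(null, full), "nested")
})

test_that("LRT null rejection rate is near the nominal level", {
  rej <- vapply(seq_len(400), function(s) {
    d <- make_lmm_data(J = 8, effect = 0, seed = 1000 + s)
    lrt_anova(fit_lmm(value ~ treatment, d),
              fit_lmm(value ~ 1, d))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.030)
  expect_lte(mean(rej), 0.075)
})

test_that("percent difference arithmetic and direction", {
  d <- make_lmm_data(seed = 6)
  f <- fit_lmm(value ~ treatment, d)
  co <- f$coefficients
  e <- percent_difference(f)
  expect_equal(e$percent, 100 * abs(co$estimate[2]) / co$estimate[1])
  expect_equal(e$direction, "higher in dark")
  expect_true(e$conf_int[1] < e$percent && e$percent < e$conf_int[2])
  # zero effect: symmetric interval around zero percent
  d0 <- d; d0$value <- rep(seq(0.28, 0.32, length.out = 8), 6)[seq_len(nrow(d))]
  f0 <- fit_lmm(value ~ treatment, make_lmm_data(effect = 0, resid_sd = 1e-6,
                                                 date_sd = 0.05, seed = 8))
  e0 <- percent_difference(f0)
  expect_lt(e0$percent, 0.01)
  expect_equal(e0$conf_int[1], -e0$conf_int[2], tolerance = 1e-2)
})

test_that("effect recovery: bias and CI coverage across simulations", {
  res <- vapply(seq_len(300), function(s) {
    d <- make_lmm_data(J = 16, mu = 0.3, effect = -0.152, seed = 2000 + s)
    e <- percent_difference(fit_lmm(value ~ treatment, d))
    c(e$percent, e$conf_int[1] <= 15.2 && 15.2 <= e$conf_int[2])
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 15.2), 1.0)
  expect_gte(mean(res[2, ]), 0.92)
  expect_lte(mean(res[2, ]), 0.98)
})

test_that("interaction model flags slope differences and handles errors", {
  gen <- function(slope_ir, seed) {
    withr::with_seed(seed, {
      J <- 16
      x <- exp(rnorm(J, 0, 0.4))
      date <- factor(rep(seq_len(J), each = 6))
      treatment <- factor(rep(rep(c("dark", "IR"), each = 3), J),
                          levels = c("dark", "IR"))
      lx <- log10(x)[as.integer(date)]
      b <- rnorm(J, 0, 0.03)
      y <- 0.3 + 0.1 * lx + (slope_ir - 0.1) * lx * (treatment == "IR") +
        b[as.integer(date)] + rnorm(J * 6, 0, 0.05)
      data.frame(value = y, treatment = treatment, date = date,
                 cov = x[as.integer(date)])
    })
  }
  # equal slopes: interaction flagged rarely
  null_flags <- vapply(1:60, function(s) {
    interaction_fit(gen(0.1, 3000 + s), "cov")$interaction_significant
  }, logical(1))
  expect_lte(mean(null_flags), 0.12)
  # strong slope difference: flagged most of the time
  alt_flags <- vapply(1:40, function(s) {
    interaction_fit(gen(0.45, 4000 + s), "cov")$interaction_significant
  }, logical(1))
  expect_gte(mean(alt_flags), 0.8)
  # per-level slope table is consistent with the coefficients
  fit <- interaction_fit(gen(0.45, 4242), "cov")
  co <- fit$fit$coefficients
  sl <- fit$levels
  expect_equal(sl$estimate[sl$level == "IR" & sl$quantity == "slope"],
               sum(co$estimate[co$term %in% c(".x", "treatmentIR:.x")]))
  d <- gen(0.1, 1); d$cov <- 5
  expect_error(interaction_fit(d, "cov"), "constant")
  d2 <- gen(0.1, 1); d2$cov <- d2$cov - 10
  expect_error(interaction_fit(d2, "cov"), "positive")
})
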