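# Random-intercept linear mixed model for the infrared-light effect.
#
# Model: y_ij = x_ij' beta + b_j + e_ij, b_j ~ N(0, sigma_d^2),
# e_ij ~ N(0, sigma^2), one grouping factor (sampling date).  Fitted by
# maximum likelihood through the profiled likelihood over the variance
# ratio lambda = sigma_d^2 / sigma^2: at each lambda the GLS estimate of
# beta and the ML residual variance are closed-form, leaving a
# one-dimensional optimization.

# Profiled ML log-likelihood machinery.  For V* = I + lambda Z Z' with a
# single grouping factor, V*^-1 is block diagonal with
# I - c 11', c = lambda / (1 + lambda n_j), and log|V*| = sum log(1 + lambda n_j).
profile_pieces <- function(y, X, group) {
  idx <- split(seq_along(y), group)
  list(
    idx = idx,
    n = length(y),
    p = ncol(X),
    nj = lengths(idx),
    XtX = crossprod(X),
    Xty = crossprod(X, y),
    yty = sum(y * y),
    Sx = do.call(rbind, lapply(idx, function(i) colSums(X[i, , drop = FALSE]))),
    Sy = vapply(idx, function(i) sum(y[i]), numeric(1))
  )
}

profile_loglik <- function(lambda, pp) {
  cj <- lambda / (1 + lambda * pp$nj)
  A <- pp$XtX - crossprod(pp$Sx * sqrt(cj))          # X' V^-1 X
  b <- pp$Xty - colSums(pp$Sx * (cj * pp$Sy))        # X' V^-1 y
  yy <- pp$yty - sum(cj * pp$Sy^2)                   # y' V^-1 y
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(list(loglik = -Inf))
  rss <- yy - sum(beta * b)
  sigma2 <- rss / pp$n
  if (sigma2 <= 0) return(list(loglik = -Inf))
  ll <- -pp$n / 2 * (log(2 * pi * sigma2) + 1) - sum(log(1 + lambda * pp$nj)) / 2
  list(loglik = ll, beta = drop(beta), sigma2 = sigma2, A = A, lambda = lambda)
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' @param formula Fixed-effects formula, e.g. `value ~ treatment`.
#' @param data data.frame containing the response, fixed-effect terms and
#'   the grouping column.
#' @param group Name of the grouping column (default `"date"`), entering as
#'   a random intercept.
#' @param reml Use REML instead of ML (default FALSE; ML matches
#'   likelihood-ratio testing of fixed effects).
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @return An object of class `mixed_fit`: `coefficients` data.frame
#'   (term, estimate, se, ci_lo, ci_hi), `vcov`, `sigma_d2`, `sigma2`,
#'   `lambda`, `loglik`, `n`, `n_groups`, `formula`.
#' @export
fit_lmm <- function(formula, data, group = "date", reml = FALSE,
                    conf_level = 0.95) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effects design matrix")
  if (!group %in% names(data)) stop("grouping column '", group, "' not found")
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (all(table(g) == 1L)) {
    stop("one observation per group: sigma_d^2 and sigma^2 are confounded ",
         "(random intercept not identifiable)")
  }
  # degenerate (noise-free) data: the fixed effects explain y exactly, the
  # likelihood is unbounded; return the exact OLS solution with zero
  # variances rather than failing
  ols <- stats::lm.fit(X, y)
  if (sum(ols$residuals^2) <= 1e-20 * max(sum(y^2), 1)) {
    est <- unname(ols$coefficients)
    coefs <- data.frame(term = colnames(X), estimate = est, se = 0,
                        ci_lo = est, ci_hi = est, row.names = NULL)
    return(structure(list(
      coefficients = coefs, vcov = matrix(0, ncol(X), ncol(X)),
      sigma_d2 = 0, sigma2 = 0, lambda = 0, loglik = Inf,
      n = length(y), n_groups = nlevels(g), n_fixed = ncol(X),
      reml = reml, conf_level = conf_level, formula = formula,
      group = group, boundary = TRUE, degenerate = TRUE
    ), class = "mixed_fit"))
  }

  pp <- profile_pieces(y, X, g)

  eval_ll <- function(lambda) {
    res <- profile_loglik(lambda, pp)
    if (reml && is.finite(res$loglik)) {
      # restricted likelihood: sigma^2 profiled with n - p and the
      # -1/2 log|X' V*^-1 X| penalty added
      rss <- res$sigma2 * pp$n
      sigma2 <- rss / (pp$n - pp$p)
      res$loglik <- -(pp$n - pp$p) / 2 * (log(2 * pi * sigma2) + 1) -
        sum(log(1 + lambda * pp$nj)) / 2 -
        determinant(res$A, logarithm = TRUE)$modulus[1] / 2
      res$sigma2 <- sigma2
    }
    res
  }
  opt <- stats::optimize(function(l) eval_ll(exp(l))$loglik,
                         interval = c(-14, 14), maximum = TRUE, tol = 1e-9)
  cand <- list(eval_ll(exp(opt$maximum)), eval_ll(0))
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "loglik"))]]
  if (!is.finite(best$loglik)) stop("mixed-model likelihood did not converge")

  vc <- best$sigma2 * solve(best$A)
  se <- sqrt(diag(vc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = colnames(X), estimate = best$beta, se = se,
                      ci_lo = best$beta - z * se, ci_hi = best$beta + z * se,
                      row.names = NULL)
  structure(list(
    coefficients = coefs, vcov = vc,
    sigma_d2 = best$lambda * best$sigma2, sigma2 = best$sigma2,
    lambda = best$lambda, loglik = best$loglik,
    n = pp$n, n_groups = nlevels(g), n_fixed = ncol(X),
    reml = reml, conf_level = conf_level,
    formula = formula, group = group,
    boundary = best$lambda < 1e-10
  ), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (%s), %d obs in %d groups, logLik %.3f\n",
              if (x$reml) "REML" else "ML", x$n, x$n_groups, x$loglik))
  print(x$coefficients, digits = 4)
  cat(sprintf("Random intercept SD %.4g, residual SD %.4g%s\n",
              sqrt(x$sigma_d2), sqrt(x$sigma2),
              if (x$boundary) " (variance ratio at boundary 0)" else ""))
  invisible(x)
}

#' @export
logLik.mixed_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_fixed + 2, class = "logLik")
}

#' Likelihood-ratio ANOVA between nested mixed-model fits
#'
#' Twice the log-likelihood difference referred to a chi-squared
#' distribution with as many degrees of freedom as the difference in fixed
#' effects.  Both fits must be ML fits of the same data.
#'
#' @param full,reduced `mixed_fit` objects, reduced nested in full.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
lrt_anova <- function(full, reduced) {
  stopifnot(inherits(full, "mixed_fit"), inherits(reduced, "mixed_fit"))
  if (full$reml || reduced$reml) {
    stop("likelihood-ratio testing of fixed effects requires ML fits")
  }
  if (full$n != reduced$n) stop("fits are not on the same data")
  if (full$n_fixed < reduced$n_fixed) stop("reduced model is not nested in full")
  if (!all(reduced$coefficients$term %in% full$coefficients$term)) {
    stop("reduced model terms are not a subset of the full model")
  }
  df <- full$n_fixed - reduced$n_fixed
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Treatment effect as a percent difference from the reference mean
#'
#' Expresses the treatment fixed effect relative to the model-implied mean
#' of the reference treatment (the intercept when treatment is the only
#' fixed term, coded with the reference first): percent =
#' 100 |beta| / mu_ref, with the interval obtained by scaling beta's Wald
#' interval by the same factor.
#'
#' @param fit A `mixed_fit` containing a treatment contrast.
#' @param term Name of the treatment coefficient; by default the first
#'   non-intercept term containing `"treatment"`.
#' @param reduced Optional nested fit without the treatment term; when
#'   given, the p-value is the likelihood-ratio ANOVA p, otherwise Wald.
#' @param reference_label,comparison_label Labels used in `direction`.
#' @return List of class `effect_summary`: `percent`, `conf_int` (percent
#'   scale, signed relative to the reported direction), `direction`,
#'   `p_value`, `estimate`, `se`, `mu_reference`.
#' @export
percent_difference <- function(fit, term = NULL, reduced = NULL,
                               reference_label = "dark",
                               comparison_label = "IR") {
  co <- fit$coefficients
  if (is.null(term)) {
    cand <- co$term[grepl("treatment", co$term) & co$term != "(Intercept)"]
    if (length(cand) == 0L) stop("no treatment coefficient found")
    term <- cand[1]
  }
  i <- match(term, co$term)
  if (is.na(i)) stop("coefficient '", term, "' not in the fit")
  mu_ref <- co$estimate[co$term == "(Intercept)"]
  if (length(mu_ref) != 1L || mu_ref <= 0) {
    stop("non-positive or missing reference mean; percent difference undefined")
  }
  beta <- co$estimate[i]; se <- co$se[i]
  z <- stats::qnorm(1 - (1 - fit$conf_level) / 2)
  s <- if (beta < 0) -1 else 1
  ci <- sort(100 * s * (beta + c(-1, 1) * z * se) / mu_ref)
  p <- if (!is.null(reduced)) lrt_anova(fit, reduced)$p_value else
    2 * stats::pnorm(-abs(beta / se))
  structure(list(
    percent = 100 * abs(beta) / mu_ref, conf_int = ci,
    direction = if (beta < 0) paste("higher in", reference_label) else
      paste("higher in", comparison_label),
    p_value = p, estimate = beta, se = se, mu_reference = mu_ref,
    term = term
  ), class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("%.1f%% (95%% CI: %.1f-%.1f%%, p = %.4g) %s\n",
              x$percent, x$conf_int[1], x$conf_int[2], x$p_value, x$direction))
  invisible(x)
}

#' Light-by-covariate interaction model
#'
#' Fits `rate ~ treatment * log10(x)` with a random date intercept, reports
#' the intercept and slope for each light level with Wald intervals, and
#' flags a significant interaction when the likelihood-ratio test against
#' the additive model gives p < alpha.
#'
#' @param data data.frame with the response, a two-level `treatment`
#'   column (reference level first) and the covariate.
#' @param covariate Name of the covariate column.
#' @param response Name of the response column (default `"value"`).
#' @param group Grouping column for the random intercept (default `"date"`).
#' @param log10_transform Apply log10 to the covariate (default TRUE);
#'   requires strictly positive values.
#' @param alpha Significance level for the interaction flag (default 0.05).
#' @return List of class `interaction_fit`: the full `fit`, `levels` table
#'   of per-level intercepts and slopes with intervals, `interaction_p`,
#'   `interaction_significant`.
#' @export
interaction_fit <- function(data, covariate, response = "value",
                            group = "date", log10_transform = TRUE,
                            alpha = 0.05) {
  x <- data[[covariate]]
  if (is.null(x)) stop("covariate '", covariate, "' not found")
  if (log10_transform) {
    if (any(x <= 0)) stop("covariate must be positive for the log10 transform")
    x <- log10(x)
  }
  if (stats::sd(x) == 0) stop("constant covariate: interaction model is rank deficient")
  d <- data
  d$.x <- x
  d$treatment <- factor(d$treatment)
  if (nlevels(d$treatment) != 2L) stop("treatment must have exactly 2 levels")
  f_full <- stats::as.formula(paste(response, "~ treatment * .x"))
  f_add <- stats::as.formula(paste(response, "~ treatment + .x"))
  full <- fit_lmm(f_full, d, group = group)
  add <- fit_lmm(f_add, d, group = group)
  test <- lrt_anova(full, add)

  co <- full$coefficients; V <- full$vcov
  lv <- levels(d$treatment)
  trt_term <- paste0("treatment", lv[2])
  int_term <- paste0("treatment", lv[2], ":.x")
  comb <- function(sel) {
    est <- sum(co$estimate[sel])
    se <- sqrt(sum(V[sel, sel]))
    z <- stats::qnorm(1 - (1 - full$conf_level) / 2)
    c(estimate = est, se = se, ci_lo = est - z * se, ci_hi = est + z * se)
  }
  rows <- rbind(
    c(level = lv[1], quantity = "intercept", comb(co$term == "(Intercept)")),
    c(level = lv[1], quantity = "slope", comb(co$term == ".x")),
    c(level = lv[2], quantity = "intercept",
      comb(co$term %in% c("(Intercept)", trt_term))),
    c(level = lv[2], quantity = "slope", comb(co$term %in% c(".x", int_term)))
  )
  levels_df <- data.frame(level = rows[, "level"], quantity = rows[, "quantity"],
                          apply(rows[, 3:6], 2, as.numeric))
  structure(list(fit = full, additive_fit = add, levels = levels_df,
                 interaction_p = test$p_value,
                 interaction_statistic = test$statistic,
                 interaction_significant = test$p_value < alpha,
                 covariate = covariate, log10 = log10_transform),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("Light x %s%s interaction: LRT p = %.4g%s\n", x$covariate,
              if (x$log10) " (log10)" else "", x$interaction_p,
              if (x$interaction_significant) " *" else ""))
  print(x$levels, digits = 4)
  invisible(x)
}
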