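test_that("rare-ASV filter applies the strict count/prevalence rule", {
  m <- matrix(3, nrow = 4, ncol = 2)           # exactly 3 everywhere: removed
  m <- cbind(m, c(4, 4, 0, 0))                 # >3 in 2 of 4 samples (50%)
  m <- cbind(m, 0)                             # all zero: removed
  colnames(m) <- paste0("a", 1:4)
  f <- rare_filter(m, min_count = 3, prevalence = 0.20)
  expect_equal(colnames(f), "a3")
  # brute-force check on a random 5 x 5 matrix
  withr::with_seed(11, m5 <- matrix(rpois(25, 3), 5, 5,
                                    dimnames = list(NULL, paste0("x", 1:5))))
  f5 <- rare_filter(m5)
  keep <- vapply(seq_len(5), function(k) sum(m5[, k] > 3) >= ceiling(0.2 * 5),
                 logical(1))
  expect_equal(colnames(f5), paste0("x", 1:5)[keep])
  # idempotent
  expect_equal(rare_filter(f5), f5)
  expect_error(rare_filter(matrix(0, 3, 3)), "no ASV")
})

test_that("variance-stabilizing transform: size factors, monotonicity, stabilization", {
  withr::with_seed(21, {
    base <- matrix(rnbinom(12 * 40, mu = 50, size = 5), 12, 40)
  })
  base[base == 0] <- 1
  same <- base[rep(1, 6), ]                  # identical samples
  # zero between-sample variance triggers the under-dispersion fallback,
  # but size factors must still be exactly one
  v <- suppressWarnings(vst_transform(same))
  expect_equal(unname(attr(v, "size_factors")), rep(1, 6))
  # strictly increasing in counts at fixed size factor
  x <- vst_transform(base)
  a <- attr(x, "dispersion")
  f <- function(z) log2(1 + 2 * a * z + 2 * sqrt(a * z * (1 + a * z))) - log2(4 * a)
  expect_true(all(diff(f(0:100)) > 0))
  # variance stabilization across a 10-fold mean gradient
  withr::with_seed(22, {
    mus <- rep(10^seq(2, 3, length.out = 8), each = 5)   # 40 taxa, 10x gradient
    counts <- sapply(mus, function(m) rnbinom(200, mu = m, size = 1 / 0.1))
  })
  tr <- vst_transform(counts)
  vt <- apply(tr, 2, var)
  vr <- apply(counts, 2, var)
  gm <- tapply(vt, rep(seq_len(8), each = 5), mean)
  expect_lt(max(gm) / min(gm) - 1, 0.25)
  expect_gt(max(vr) / min(vr), 4)
  # under-dispersed input falls back to a log transform with a warning
  withr::with_seed(23, und <- matrix(rpois(200, 100), 20, 10))
  expect_warning(vst_transform(und), "dispersion")
})

test_that("Bray-Curtis dissimilarity: hand values and clipping", {
  x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], 4 / 12)
  expect_equal(diag(d), c(a = 0, b = 0))
  same <- rbind(c(2, 5, 1), c(2, 5, 1))
  expect_equal(bray_curtis(same)[1, 2], 0)
  disjoint <- rbind(c(1, 1, 0, 0), c(0, 0, 2, 2))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
  # matches the direct formula on random data
  withr::with_seed(31, m <- matrix(rexp(40), 5, 8))
  d5 <- bray_curtis(m)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d5[i, j], sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ]))
  }
  expect_warning(bray_curtis(rbind(c(-1, 2, 5), c(1, 2, 3))), "clipped")
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 2))), "all-zero")
})

test_that("pseudo-F on a Euclidean distance equals the classical F", {
  withr::with_seed(41, {
    x <- rnorm(15)
    y <- 2 + 0.7 * x + rnorm(15)
  })
  d <- as.matrix(dist(y))
  res <- distlm(d, data.frame(x = x), n_perms = 99, seed = 5)
  f_classic <- unname(summary(lm(y ~ x))$fstatistic[1])
  expect_equal(res$marginal$pseudo_f, f_classic, tolerance = 1e-9)
  expect_equal(res$marginal$explained_pct / 100,
               summary(lm(y ~ x))$r.squared, tolerance = 1e-9)
})

test_that("exact permutation p matches exhaustive enumeration", {
  y <- c(1.0, 3.1, 2.2, 5.3, 4.1)
  x <- c(0.2, 1.1, 0.7, 2.0, 1.4)
  d <- as.matrix(dist(y))
  res <- distlm(d, data.frame(x = x), n_perms = "exact")
  # independent oracle: enumerate all 120 label permutations, classical F
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perms(v[-i]))
    }))
  }
  P <- perms(1:5)
  f_obs <- unname(summary(lm(y ~ x))$fstatistic[1])
  f_all <- apply(P, 1, function(p) unname(summary(lm(y[p] ~ x))$fstatistic[1]))
  expect_equal(res$marginal$p, mean(f_all >= f_obs - 1e-12))
  expect_equal(res$n_perms, 120)
})

test_that("distlm type-I error is near nominal under the null", {
  rej <- vapply(seq_len(200), function(s) {
    withr::with_seed(5000 + s, {
      y <- matrix(rnorm(20 * 6), 20, 6)
      x <- rnorm(20)
    })
    d <- as.matrix(dist(y))
    distlm(d, data.frame(x = x), n_perms = 99, seed = s,
           select = "none")$marginal$p <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("distlm is reproducible and validates inputs", {
  withr::with_seed(51, {
    y <- matrix(rnorm(30), 10, 3); x <- data.frame(a = rnorm(10), b = rnorm(10))
  })
  d <- as.matrix(dist(y))
  r1 <- distlm(d, x, n_perms = 199, seed = 7)
  r2 <- distlm(d, x, n_perms = 199, seed = 7)
  expect_identical(r1$marginal, r2$marginal)
  expect_error(distlm(d[1:9, 1:10], x), "symmetric")
  expect_error(distlm(d, data.frame(a = rep(1, 10))), "constant")
  expect_error(distlm(d[1:4, 1:4], x[1:4, ]), "at least 5")
})

test_that("orthogonal decomposition of the Gower matrix holds", {
  withr::with_seed(61, {
    y <- matrix(rexp(48), 12, 4)
    x <- data.frame(a = rnorm(12), b = runif(12))
  })
  d <- suppressWarnings(bray_curtis(y))
  g <- aapflux:::gower_center(d)
  h <- aapflux:::hat_matrix(scale(as.matrix(x)))
  i_h <- diag(12) - h
  expect_equal(sum(diag(g)),
               sum(diag(h %*% g %*% h)) + sum(diag(i_h %*% g %*% i_h)),
               tolerance = 1e-9)
})

test_that("dbRDA: spectral identity and Euclidean equivalence", {
  withr::with_seed(71, {
    y <- matrix(rnorm(20 * 4), 20, 4)
    x <- data.frame(a = rnorm(20), b = rnorm(20))
  })
  d <- as.matrix(dist(y))
  db <- dbrda(d, x)
  expect_equal(sum(db$eigenvalues), db$ss_fit, tolerance = 1e-9)
  # Euclidean D: axes equal the eigen-structure of the fitted values' Gram matrix
  h <- aapflux:::hat_matrix(scale(as.matrix(x)))
  yc <- scale(y, scale = FALSE)
  fitted <- h %*% yc
  ref <- eigen(tcrossprod(fitted), symmetric = TRUE)
  k <- length(db$eigenvalues)
  expect_equal(db$eigenvalues, ref$values[seq_len(k)], tolerance = 1e-8)
  for (ax in 1:2) {
    ref_score <- ref$vectors[, ax] * sqrt(ref$values[ax])
    expect_equal(abs(cor(db$scores[, ax], ref_score)), 1, tolerance = 1e-8)
  }
  # two samples: a single axis, symmetric about zero
  d2 <- as.matrix(dist(c(0, 3)))
  # (hat matrix on 2 points with 1 predictor is saturated; use 3 points)
  d3 <- as.matrix(dist(c(0, 1, 3)))
  db3 <- dbrda(d3, data.frame(a = c(0, 1, 2.5)))
  expect_equal(sum(db3$scores[, 1]), 0, tolerance = 1e-9)
})
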