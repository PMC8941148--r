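# Community composition analysis: prevalence filtering of ASV counts, a
# negative-binomial variance-stabilizing transform (common dispersion),
# Bray-Curtis dissimilarity, distance-based linear models (DistLM) with
# permutation inference, and distance-based redundancy analysis (dbRDA).

#' Remove rare ASVs by a count/prevalence rule
#'
#' An ASV is retained if and only if its count strictly exceeds `min_count`
#' in at least `ceiling(prevalence * n_samples)` samples.
#'
#' @param counts Matrix of non-negative integers, samples in rows, ASVs in
#'   columns.
#' @param min_count Count that must be exceeded (default 3, exclusive).
#' @param prevalence Fraction of samples (default 0.20).
#' @return The filtered count matrix.
#' @export
rare_filter <- function(counts, min_count = 3, prevalence = 0.20) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  need <- ceiling(prevalence * nrow(counts))
  keep <- colSums(counts > min_count) >= need
  if (!any(keep)) {
    stop("no ASV passes the filter (min_count = ", min_count,
         ", prevalence = ", prevalence, ", needs >", min_count,
         " in >= ", need, " of ", nrow(counts), " samples)")
  }
  counts[, keep, drop = FALSE]
}

# Median-of-ratios size factors (computed on ASVs observed in every sample).
size_factors <- function(counts) {
  pos <- colSums(counts == 0) == 0
  if (!any(pos)) stop("no ASV is present in all samples; cannot compute size factors")
  logc <- log(counts[, pos, drop = FALSE])
  ref <- colMeans(logc)                      # log geometric mean per ASV
  apply(logc, 1, function(r) exp(stats::median(r - ref)))
}

#' Negative-binomial variance-stabilizing transform with common dispersion
#'
#' Normalizes counts by median-of-ratios size factors, estimates a single
#' (common) dispersion by the method of moments on the normalized counts,
#' and applies the closed-form variance-stabilizing transform of the
#' negative-binomial family with constant dispersion alpha,
#' f(x) = log2(1 + 2 a x + 2 sqrt(a x (1 + a x))) - log2(4 a),
#' which behaves like log2(x) for large counts.  This is a self-contained
#' re-derivation of the common-dispersion case, intended for downstream
#' resemblance analysis rather than bit-exact agreement with any particular
#' count-model package.
#'
#' @param counts Samples x ASVs matrix of non-negative counts.
#' @return Transformed matrix with attributes `size_factors` and
#'   `dispersion`.  Falls back to log2(x/s + 1) with a warning when the
#'   moment estimate of the dispersion is non-positive (under-dispersion).
#' @export
vst_transform <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  s <- size_factors(counts)
  norm <- sweep(counts, 1, s, "/")
  m <- colMeans(norm)
  v <- apply(norm, 2, stats::var)
  ok <- m > 0
  alpha <- stats::median((v[ok] - m[ok]) / m[ok]^2)
  if (!is.finite(alpha) || alpha <= 0) {
    warning("non-positive common dispersion estimate; falling back to log2(x/s + 1)")
    out <- log2(norm + 1)
    attr(out, "size_factors") <- s
    attr(out, "dispersion") <- NA_real_
    return(out)
  }
  ax <- alpha * norm
  out <- log2(1 + 2 * ax + 2 * sqrt(ax * (1 + ax))) - log2(4 * alpha)
  attr(out, "size_factors") <- s
  attr(out, "dispersion") <- alpha
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(i, j) = sum|x_ik - x_jk| / sum(x_ik + x_jk).  Negative entries (as can
#' arise from a variance-stabilizing transform) are clipped to zero with a
#' warning, since Bray-Curtis requires non-negative abundances.
#'
#' @param x Samples x features matrix.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) {
    warning("negative entries clipped to 0 before Bray-Curtis")
    x[x < 0] <- 0
  }
  if (any(rowSums(x) == 0) && sum(rowSums(x) == 0) >= 2) {
    stop("Bray-Curtis undefined: two or more all-zero samples")
  }
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

# Gower-centered inner-product matrix G = -1/2 J (D o D) J.
gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

# Hat matrix of [1, X]; X columns standardized by the caller.
hat_matrix <- function(x) {
  xm <- cbind(1, as.matrix(x))
  q <- qr(xm)
  if (q$rank < ncol(xm)) stop("constant or collinear predictor")
  qq <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(qq)
}

pseudo_f <- function(g, h, n, m) {
  ss_fit <- sum(diag(h %*% g %*% h))
  ss_res <- sum(diag(g)) - ss_fit
  list(f = (ss_fit / m) / (ss_res / (n - m - 1)), ss_fit = ss_fit,
       ss_tot = sum(diag(g)))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Distance-based linear model with permutation tests
#'
#' Regresses a dissimilarity matrix on predictors through the Gower-centered
#' inner-product matrix (McArdle-Anderson partitioning).  Marginal tests use
#' unrestricted permutation of sample labels; sequential tests during
#' forward selection use Freedman-Lane residual permutation under the
#' reduced model.  Forward selection maximizes adjusted R^2 (AIC available).
#'
#' @param d Symmetric dissimilarity matrix.
#' @param x data.frame or matrix of predictors (standardized internally).
#' @param n_perms Number of permutations (default 999), or `"exact"` to
#'   enumerate all n! permutations (n <= 8).
#' @param seed Integer seed for the permutation stream.
#' @param select Forward-selection criterion: `"adjR2"` (default) or
#'   `"aic"`; `"none"` skips selection.
#' @return A list of class `distlm_result`: `marginal` data.frame
#'   (predictor, pseudo_f, explained_pct, p), `selection` data.frame (the
#'   forward trace with sequential pseudo-F and p), `total_explained_pct`
#'   for the selected set, `n_perms`, `seed`.
#' @export
distlm <- function(d, x, n_perms = 999, seed = 1,
                   select = c("adjR2", "aic", "none")) {
  select <- match.arg(select)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
  x <- as.data.frame(x)
  if (anyNA(x) || anyNA(d)) stop("missing values are not supported")
  n <- nrow(d)
  if (n < 5) stop("need at least 5 samples")
  if (nrow(x) != n) stop("predictor rows must match the dissimilarity matrix")
  xs <- scale(as.matrix(x))
  if (any(!is.finite(xs))) stop("constant predictor")
  g <- gower_center(d)
  ss_tot <- sum(diag(g))

  exact <- identical(n_perms, "exact")
  perms <- if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    all_permutations(n)
  } else {
    withr::with_seed(seed, t(replicate(n_perms, sample.int(n))))
  }

  marginal <- do.call(rbind, lapply(names(x), function(v) {
    h <- hat_matrix(xs[, v, drop = FALSE])
    obs <- pseudo_f(g, h, n, 1)
    fp <- apply(perms, 1, function(p) pseudo_f(g[p, p], h, n, 1)$f)
    pval <- if (exact) mean(fp >= obs$f - 1e-12) else
      (1 + sum(fp >= obs$f - 1e-12)) / (length(fp) + 1)
    data.frame(predictor = v, pseudo_f = obs$f,
               explained_pct = 100 * obs$ss_fit / ss_tot, p = pval)
  }))
  rownames(marginal) <- NULL

  selection <- NULL
  selected <- character(0)
  if (select != "none") {
    adj_r2 <- function(vars) {
      m <- length(vars)
      h <- hat_matrix(xs[, vars, drop = FALSE])
      r2 <- sum(diag(h %*% g %*% h)) / ss_tot
      list(r2 = r2, adj = 1 - (1 - r2) * (n - 1) / (n - m - 1),
           aic = n * log(1 - r2) + 2 * m, h = h)
    }
    crit <- function(fit) if (select == "adjR2") fit$adj else -fit$aic
    best_val <- if (select == "adjR2") 0 else -n * log(1) - 0  # null criterion
    rows <- list()
    remaining <- names(x)
    h_red <- matrix(1 / n, n, n)             # intercept-only hat matrix
    repeat {
      fits <- lapply(remaining, function(v) adj_r2(c(selected, v)))
      vals <- vapply(fits, crit, numeric(1))
      k <- which.max(vals)
      if (vals[k] <= best_val || length(remaining) == 0L) break
      v <- remaining[k]; fit <- fits[[k]]
      m_full <- length(selected) + 1L
      h_full <- fit$h
      obs_fit <- sum(diag(h_full %*% g %*% h_full))
      red_fit <- sum(diag(h_red %*% g %*% h_red))
      f_seq <- (obs_fit - red_fit) /
        ((ss_tot - obs_fit) / (n - m_full - 1))
      # Freedman-Lane: permute the residual inner-product matrix under the
      # reduced model, keep the fitted part
      r <- diag(n) - h_red
      e <- r %*% g %*% r
      fitted_part <- g - e
      fp <- apply(perms, 1, function(p) {
        gp <- fitted_part + e[p, p]
        of <- sum(diag(h_full %*% gp %*% h_full))
        rf <- sum(diag(h_red %*% gp %*% h_red))
        (of - rf) / ((sum(diag(gp)) - of) / (n - m_full - 1))
      })
      pval <- if (exact) mean(fp >= f_seq - 1e-12) else
        (1 + sum(fp >= f_seq - 1e-12)) / (length(fp) + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        step = length(rows) + 1L, predictor = v, pseudo_f = f_seq, p = pval,
        adj_r2 = fit$adj, cumulative_pct = 100 * fit$r2)
      selected <- c(selected, v)
      remaining <- setdiff(remaining, v)
      best_val <- vals[k]
      h_red <- h_full
      if (length(remaining) == 0L) break
    }
    selection <- if (length(rows)) do.call(rbind, rows) else
      data.frame(step = integer(), predictor = character(),
                 pseudo_f = numeric(), p = numeric(), adj_r2 = numeric(),
                 cumulative_pct = numeric())
  }
  total <- if (length(selected)) {
    h <- hat_matrix(xs[, selected, drop = FALSE])
    100 * sum(diag(h %*% g %*% h)) / ss_tot
  } else NA_real_
  structure(list(marginal = marginal, selection = selection,
                 selected = selected, total_explained_pct = total,
                 n_perms = if (exact) nrow(perms) else n_perms,
                 exact = exact, seed = seed, n = n),
            class = "distlm_result")
}

#' @export
print.distlm_result <- function(x, ...) {
  cat(sprintf("DistLM on %d samples, %s permutations (seed %d)\n", x$n,
              if (x$exact) paste0("all ", x$n_perms) else x$n_perms, x$seed))
  cat("Marginal tests:\n"); print(x$marginal, digits = 4)
  if (!is.null(x$selection) && nrow(x$selection)) {
    cat("Forward selection:\n"); print(x$selection, digits = 4)
    cat(sprintf("Selected set explains %.1f%% of the total variation\n",
                x$total_explained_pct))
  }
  invisible(x)
}

#' Distance-based redundancy analysis ordination
#'
#' Eigen-decomposition of the fitted inner-product matrix H G H for a
#' selected predictor set; sample scores are eigenvectors scaled by the
#' square roots of the (positive) eigenvalues, and predictor biplot vectors
#' are correlations of the standardized predictors with the axis scores.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param x Predictor data.frame/matrix (the selected set).
#' @return List of class `dbrda_result`: `eigenvalues`, `scores`
#'   (samples x axes), `biplot` (predictors x axes), `ss_fit`.
#' @export
dbrda <- function(d, x) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
  x <- as.data.frame(x)
  xs <- scale(as.matrix(x))
  g <- gower_center(d)
  h <- hat_matrix(xs)
  hgh <- h %*% g %*% h
  hgh <- (hgh + t(hgh)) / 2
  eig <- eigen(hgh, symmetric = TRUE)
  pos <- eig$values > max(eig$values, 0) * 1e-10
  if (!any(pos) || max(eig$values) <= 0) stop("degenerate fit: no positive eigenvalues")
  ev <- eig$values[pos]
  v <- eig$vectors[, pos, drop = FALSE]
  scores <- sweep(v, 2, sqrt(ev), "*")
  colnames(scores) <- paste0("dbRDA", seq_along(ev))
  rownames(scores) <- rownames(d)
  bip <- stats::cor(xs, scores)
  structure(list(eigenvalues = ev, scores = scores, biplot = bip,
                 ss_fit = sum(diag(hgh))),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat("dbRDA ordination:", length(x$eigenvalues), "positive axes\n")
  cat("Eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}
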