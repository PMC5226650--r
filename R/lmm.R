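# Single-marker mixed-model association: centered-IBS kinship, EMMA-style
# spectral REML for the null model, and a GLS marker scan with either a
# shared variance ratio (fast, EMMAX-like) or per-marker re-estimation.

#' Estimate a centered-IBS kinship matrix
#'
#' K = (1/m) * sum over polymorphic markers of outer products of
#' centered-standardized dosages, rescaled so the mean diagonal equals 1.
#' Missing dosages are mean-imputed per marker.
#'
#' @param G a [genotype_matrix()] or dosage matrix (lines x markers).
#' @param method currently only `"centered_ibs"`.
#' @return n x n symmetric kinship matrix with line-id dimnames.
#' @export
estimate_kinship <- function(G, method = "centered_ibs") {
  method <- match.arg(method, "centered_ibs")
  d <- if (inherits(G, "genotype_matrix")) G$dosage else as.matrix(G)
  if (nrow(d) < 2) stop("need at least two lines", call. = FALSE)
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  sds <- apply(d, 2, stats::sd)
  poly <- sds > 0
  if (!any(poly)) stop("all markers are monomorphic", call. = FALSE)
  Z <- scale(d[, poly, drop = FALSE])
  K <- tcrossprod(Z) / ncol(Z)
  K <- K / mean(diag(K))
  dimnames(K) <- list(rownames(d), rownames(d))
  K
}

# Spectral workspace shared by the REML fit and the scans.
kinship_eigen <- function(K, tol = 1e-8) {
  if (inherits(K, "kinship_eigen")) return(K)
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-10) {
    stop("kinship matrix is not symmetric", call. = FALSE)
  }
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -tol * max(1, max(e$values))) {
    stop("kinship matrix is not positive semi-definite", call. = FALSE)
  }
  structure(list(values = pmax(e$values, 0), vectors = e$vectors, K = K),
            class = "kinship_eigen")
}

# Restricted (or full) log-likelihood for H = K + delta I, sigma_g2 profiled
# out.  Operates on rotated responses/designs (columns of U' X, U' y).
rotated_loglik <- function(delta, lam, ys, Xs, logdet_XtX, method = "reml") {
  n <- length(ys)
  w <- 1 / (lam + delta)
  sw <- sqrt(w)
  Xw <- Xs * sw
  yw <- ys * sw
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  p <- fit$rank
  if (method == "reml") {
    R <- qr.R(fit$qr)
    logdet_XtHX <- 2 * sum(log(abs(diag(R))))
    -0.5 * ((n - p) * log(2 * pi * rss / (n - p)) + (n - p) +
              sum(log(lam + delta)) + logdet_XtHX - logdet_XtX)
  } else {
    -0.5 * (n * log(2 * pi * rss / n) + n + sum(log(lam + delta)))
  }
}

optimize_delta <- function(lam, ys, Xs, logdet_XtX, method = "reml",
                           grid_n = 121) {
  grid <- 10^seq(-5, 5, length.out = grid_n)
  ll <- vapply(grid, rotated_loglik, numeric(1), lam = lam, ys = ys, Xs = Xs,
               logdet_XtX = logdet_XtX, method = method)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(ld) {
    rotated_loglik(exp(ld), lam, ys, Xs, logdet_XtX, method)
  }, lower = log(lo), upper = log(hi), maximum = TRUE, tol = 1e-10)
  delta <- exp(opt$maximum)
  if (opt$objective < ll[i]) delta <- grid[i]  # guard against flat ridges
  list(delta = delta,
       loglik = max(opt$objective, ll[i]))
}

#' Fit the null linear mixed model by spectral REML
#'
#' Model: y = X beta + u + e with var(u) = sigma_g2 K, var(e) = sigma_e2 I.
#' The kinship is eigendecomposed once and the restricted likelihood is
#' maximized over delta = sigma_e2/sigma_g2 on a log grid refined by
#' golden-section search.
#'
#' @param y numeric phenotype vector.
#' @param K kinship matrix (or a precomputed spectral workspace).
#' @param X covariate design matrix; an intercept is prepended when absent.
#' @return list of class `lmm_fit`: `sigma_g2`, `sigma_e2`, `delta`,
#'   `loglik` (restricted), `h2`, `identifiable` (FALSE when K is the
#'   identity, in which case only the total variance is estimable), plus the
#'   rotated workspace used by the scans.
#' @export
fit_null_lmm <- function(y, K, X = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  ek <- kinship_eigen(K)
  if (nrow(ek$vectors) != n) stop("y and K dimensions differ", call. = FALSE)
  X <- build_design(X, n)
  if (qr(X)$rank < ncol(X)) {
    stop("covariate design matrix is singular", call. = FALSE)
  }
  if (n <= ncol(X) + 1) stop("too few lines for the design", call. = FALSE)
  Ut <- t(ek$vectors)
  ys <- drop(Ut %*% y)
  Xs <- Ut %*% X
  logdet_XtX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  identifiable <- max(abs(ek$K - diag(n))) > 1e-8
  opt <- optimize_delta(ek$values, ys, Xs, logdet_XtX, "reml")
  delta <- opt$delta
  w <- 1 / (ek$values + delta)
  fit <- stats::lm.fit(Xs * sqrt(w), ys * sqrt(w))
  rss <- sum(fit$residuals^2)
  sigma_g2 <- rss / (n - fit$rank)
  out <- list(sigma_g2 = sigma_g2, sigma_e2 = sigma_g2 * delta,
              delta = delta, loglik = opt$loglik,
              h2 = 1 / (1 + delta), identifiable = identifiable,
              n = n, beta = fit$coefficients,
              eigen = ek, ys = ys, Xs = Xs, X = X, y = y,
              logdet_XtX = logdet_XtX)
  if (!identifiable) {
    warning("kinship is (numerically) the identity: only sigma_g2 + sigma_e2 ",
            "is identifiable", call. = FALSE)
  }
  class(out) <- "lmm_fit"
  out
}

build_design <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  has_intercept <- any(apply(X, 2, function(col) all(col == col[1] & col != 0)))
  if (!has_intercept) X <- cbind(intercept = 1, X)
  X
}

# Vectorized GLS F-tests of each column of Gs (rotated markers) added to the
# null design, at a fixed delta.  Returns beta, F p-values.
gls_marker_tests <- function(null_fit, Gs, delta = null_fit$delta) {
  lam <- null_fit$eigen$values
  w <- 1 / (lam + delta)
  sw <- sqrt(w)
  Xw <- null_fit$Xs * sw
  yw <- null_fit$ys * sw
  qrX <- qr(Xw)
  p0 <- qrX$rank
  n <- length(yw)
  ry <- qr.resid(qrX, yw)
  RG <- qr.resid(qrX, Gs * sw)
  gg <- colSums(RG^2)
  gy <- colSums(RG * ry)
  rss0 <- sum(ry^2)
  ok <- gg > 1e-12
  beta <- ifelse(ok, gy / gg, NA_real_)
  rss1 <- rss0 - ifelse(ok, gy^2 / gg, 0)
  df <- n - p0 - 1
  fstat <- (rss0 - rss1) / (rss1 / df)
  p <- ifelse(ok, stats::pf(fstat, 1, df, lower.tail = FALSE), 1)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(beta = beta, p = p, rss0 = rss0, rss1 = rss1, df = df, ok = ok)
}

#' Single-marker mixed-model association scan
#'
#' Each marker is tested by generalized least squares in the eigenbasis of
#' the kinship.  With `refit_delta = FALSE` (the default, EMMAX-like fast
#' path) the null model's variance ratio is reused for every marker; with
#' `refit_delta = TRUE` the ratio is re-optimized per marker (exact mode).
#' Monomorphic markers are reported with MAF 0 and p-value 1.
#'
#' @param y phenotype vector.
#' @param G a [genotype_matrix()].
#' @param K kinship matrix.
#' @param X optional covariate matrix (columns beyond the intercept, e.g.
#'   conditioning markers).
#' @param refit_delta logical; re-optimize the variance ratio per marker.
#' @param markers optional marker ids or column indices restricting the scan.
#' @return data.frame with `id`, `chrom`, `pos`, `maf`, `beta`, `p`,
#'   `neg_log10_p`, ordered by position.
#' @export
scan_single_marker <- function(y, G, K, X = NULL, refit_delta = FALSE,
                               markers = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  null_fit <- if (inherits(K, "lmm_fit")) K else fit_null_lmm(y, K, X)
  cols <- resolve_markers(G, markers)
  D <- G$dosage[, cols, drop = FALSE]
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  Ut <- t(null_fit$eigen$vectors)
  Gs <- Ut %*% D
  tests <- gls_marker_tests(null_fit, Gs)
  beta <- tests$beta
  p <- tests$p
  if (refit_delta) {
    lam <- null_fit$eigen$values
    for (j in seq_len(ncol(Gs))) {
      if (!tests$ok[j]) next
      Xj <- cbind(null_fit$Xs, Gs[, j])
      XtX <- as.numeric(determinant(
        crossprod(cbind(null_fit$X, D[, j])), logarithm = TRUE)$modulus)
      opt <- optimize_delta(lam, null_fit$ys, Xj, XtX, "reml")
      tj <- gls_marker_tests(null_fit, Gs[, j, drop = FALSE],
                             delta = opt$delta)
      beta[j] <- tj$beta
      p[j] <- tj$p
    }
  }
  maf <- marker_maf(D)
  mono <- apply(D, 2, function(col) stats::var(col) == 0)
  p[mono] <- 1
  beta[mono] <- NA_real_
  out <- data.frame(id = G$map$id[cols], chrom = G$map$chrom[cols],
                    pos = G$map$pos[cols], maf = maf, beta = beta, p = p,
                    neg_log10_p = -log10(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(as.character(out$chrom), out$pos, out$id), , drop = FALSE]
}

resolve_markers <- function(G, markers) {
  if (is.null(markers)) return(seq_len(ncol(G$dosage)))
  if (is.character(markers)) {
    cols <- match(markers, G$map$id)
    if (anyNA(cols)) {
      stop("unknown marker id(s): ",
           paste(markers[is.na(cols)], collapse = ", "), call. = FALSE)
    }
    cols
  } else {
    as.integer(markers)
  }
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return per-test p-value threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  check_fraction(alpha, "alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  n_tests <- check_count(n_tests, "n_tests")
  alpha / n_tests
}

#' Genomic inflation factor
#'
#' Median of the chi-square statistics implied by a vector of p-values,
#' divided by the null median (0.4549).
#'
#' @param p vector of p-values.
#' @return lambda, the genomic inflation factor.
#' @export
genomic_inflation <- function(p) {
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}
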