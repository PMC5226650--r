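# Partial Mantel test: phenotype-distance vs environment-distance
# association controlling for a relatedness distance.

#' Convert a similarity (kinship) matrix to a distance matrix
#'
#' `max(K) - K`, with the diagonal zeroed — an order-preserving conversion.
#'
#' @param K similarity matrix.
#' @return distance matrix of the same dimension.
#' @export
similarity_to_distance <- function(K) {
  K <- as.matrix(K)
  D <- max(K) - K
  diag(D) <- 0
  D
}

check_distance_matrix <- function(d, name) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop(sprintf("`%s` must be a symmetric square matrix", name),
         call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-8)) {
    stop(sprintf("`%s` must have a zero diagonal", name), call. = FALSE)
  }
  d
}

mantel_stat <- function(vp, ve, vc) {
  rp <- stats::residuals(stats::lm.fit(cbind(1, rank(vc)),
                                       rank(vp)))
  re <- stats::residuals(stats::lm.fit(cbind(1, rank(vc)),
                                       rank(ve)))
  stats::cor(rp, re)
}

#' Partial Mantel test with Spearman correlation
#'
#' Spearman correlation between the off-diagonal entries of a phenotype
#' distance matrix and an environment distance matrix, each residualized
#' (on the rank scale) on a covariate distance matrix — equivalently, the
#' partial Spearman correlation.  The p-value permutes the row/column
#' labels of the dependent (phenotype) matrix jointly:
#' `p = (#\{|perm| >= |obs|\} + 1) / (n_perm + 1)`.
#'
#' @param d_pheno,d_env,d_covar conformable symmetric distance matrices
#'   with zero diagonals.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed; the result is deterministic given it.
#' @return list with `coefficient` and `p_value`.
#' @export
partial_mantel <- function(d_pheno, d_env, d_covar, n_perm = 999, seed = 1) {
  d_pheno <- check_distance_matrix(d_pheno, "d_pheno")
  d_env <- check_distance_matrix(d_env, "d_env")
  d_covar <- check_distance_matrix(d_covar, "d_covar")
  n <- nrow(d_pheno)
  stopifnot(nrow(d_env) == n, nrow(d_covar) == n)
  n_perm <- check_count(n_perm, "n_perm", min = 99)
  ve <- offdiag(d_env)
  vc <- offdiag(d_covar)
  obs <- mantel_stat(offdiag(d_pheno), ve, vc)
  perm_ge <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      abs(mantel_stat(offdiag(d_pheno[idx, idx]), ve, vc)) >= abs(obs)
    }, logical(1)))
  })
  list(coefficient = obs, p_value = (perm_ge + 1) / (n_perm + 1))
}
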