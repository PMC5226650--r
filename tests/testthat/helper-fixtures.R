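# Builders shared across test files; everything is generated in code.

# Small genotype matrix with an explicit map.
tiny_G <- function(dosage, chrom = "1", pos = NULL, ids = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100
  if (is.null(ids)) ids <- sprintf("m%02d", seq_len(m))
  genotype_matrix(dosage,
                  data.frame(id = ids, chrom = rep_len(chrom, m), pos = pos))
}

# Structured panel with the heterogeneous locus planted and a phenotype.
planted_panel <- function(seed, n_lines = 200, n_markers = 2000,
                          spec = locus_spec(), ...) {
  pc <- population_config(n_lines = n_lines, n_markers = n_markers,
                          seed = seed, ...)
  G <- simulate_structured_genotypes(pc)
  G <- plant_heterogeneity_locus(G, spec, seed = seed + 5000)
  y <- simulate_phenotype(G, spec, seed = seed + 9000)
  list(G = G, y = y, spec = spec, region = pc$region)
}

# Independent dense-matrix REML restricted log-likelihood (no spectral
# shortcut); the brute-force oracle for the LMM fits.
reml_loglik_direct <- function(delta, y, K, X = matrix(1, length(y), 1)) {
  n <- length(y)
  p <- ncol(X)
  V <- K + delta * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  as.numeric(-0.5 * ((n - p) * log(2 * pi * rss / (n - p)) + (n - p) +
                       determinant(V)$modulus + determinant(XtViX)$modulus -
                       determinant(t(X) %*% X)$modulus))
}

# Independent dense-matrix ML log-likelihood (for the extBIC null check).
ml_loglik_direct <- function(delta, y, K, X = matrix(1, length(y), 1)) {
  n <- length(y)
  V <- K + delta * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  as.numeric(-0.5 * (n * log(2 * pi * rss / n) + n +
                       determinant(V)$modulus))
}

# Correlated phenotype with known variance components on a given kinship.
draw_mvn_pheno <- function(K, sigma_g2, sigma_e2) {
  n <- nrow(K)
  g <- drop(t(chol(K + diag(1e-6, n))) %*% rnorm(n))
  sqrt(sigma_g2) * g + rnorm(n, sd = sqrt(sigma_e2))
}

# Random symmetric distance matrix with zero diagonal.
random_dist <- function(n) {
  m <- matrix(runif(n * n), n)
  m <- m + t(m)
  diag(m) <- 0
  m
}
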