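# Heterogeneity machinery: pseudo-SNP construction and scan, the stepwise
# multi-locus model with extBIC, and haplogroup calls.

test_that("pseudo-SNPs implement the OR truth table over all unordered pairs", {
  d <- cbind(a = c(0, 0, 1, 1, 0, 1, 0, 1, 0, 0),
             b = c(0, 1, 0, 1, 1, 0, 0, 0, 1, 0),
             c = c(1, 0, 0, 0, 0, 0, 1, 0, 0, 1))
  G <- tiny_G(d, chrom = "5", pos = c(100, 200, 300))
  ps <- make_pseudo_snps(G, "5:1-1000", maf_min = 0.05)
  expect_equal(unname(ps$counts), c(3, 3, 3))
  expect_equal(nrow(ps$pairs), 3)
  expect_true(all(ps$pairs[, 1] < ps$pairs[, 2]))  # no self-pairs
  expect_equal(pseudo_dosage(ps, 1), as.integer(d[, "a"] | d[, "b"]))
  # the published truth table: (0,0,1) OR (0,1,0) = (0,1,1)
  G2 <- tiny_G(cbind(x = c(0, 0, 1), y = c(0, 1, 0)), chrom = "5")
  ps2 <- make_pseudo_snps(G2, "5:1-1000")
  expect_equal(pseudo_dosage(ps2, 1), c(0L, 1L, 1L))
  expect_equal(unname(ps2$counts[["pairs"]]), 1)
})

test_that("pair count is m(m-1)/2 and the MAF filter is enforced", {
  set.seed(8)
  d <- matrix(rbinom(40 * 12, 1, 0.5), 40)
  G <- tiny_G(d, chrom = "5", pos = 1:12 * 10)
  ps <- make_pseudo_snps(G, "5:1-1000")
  expect_equal(unname(ps$counts[["pairs"]]), 66)  # C(12, 2)
  # rare markers are discarded before pairing
  d2 <- cbind(d, rare = c(1, rep(0, 39)))  # MAF 0.025 < 0.05
  G2 <- tiny_G(d2, chrom = "5", pos = 1:13 * 10)
  ps2 <- make_pseudo_snps(G2, "5:1-1000")
  expect_equal(ps2$counts,
               c(markers_in_region = 13, markers_passing = 12, pairs = 66))
  expect_error(make_pseudo_snps(tiny_G(d[, 1, drop = FALSE], chrom = "5"),
                                "5:1-1000"), ">= 2")
})

test_that("pseudo-SNP scan agrees pair-for-pair with an explicit OR loop", {
  pp <- planted_panel(101, n_lines = 120, n_markers = 300,
                      n_region_markers = 10)
  K <- estimate_kinship(pp$G)
  ps <- make_pseudo_snps(pp$G, pp$region)
  res <- scan_pseudo_snps(pp$y, ps, K)
  expect_false(is.unsorted(res$p))
  # oracle: build each OR vector explicitly and push it through the
  # single-marker scan
  fit <- fit_null_lmm(pp$y, K)
  for (k in seq_len(nrow(ps$pairs))) {
    or_vec <- pseudo_dosage(ps, k)
    Gor <- tiny_G(cbind(or_vec, 0L), chrom = "9")
    single <- scan_single_marker(pp$y, Gor, fit, markers = 1)
    row <- res[res$id_i == ps$ids[ps$pairs[k, 1]] &
                 res$id_j == ps$ids[ps$pairs[k, 2]], ]
    if (var(or_vec) == 0) {
      expect_equal(row$p, 1)
    } else {
      expect_equal(row$p, single$p, tolerance = 1e-9)
      expect_equal(row$beta, single$beta, tolerance = 1e-9)
    }
  }
})

test_that("ORing a marker with its duplicate reproduces the marker's own test", {
  pp <- planted_panel(102, n_lines = 100, n_markers = 300,
                      n_region_markers = 6)
  G <- pp$G
  # duplicate SNP2 at a new position inside the region
  j <- which(G$map$id == "SNP2")
  G$dosage <- cbind(G$dosage, SNP2copy = G$dosage[, j])
  G$map <- rbind(G$map, data.frame(id = "SNP2copy", chrom = "5",
                                   pos = 18592366))
  K <- estimate_kinship(pp$G)
  ps <- make_pseudo_snps(G, pp$region)
  res <- scan_pseudo_snps(pp$y, ps, K)
  row <- res[res$id_i == "SNP2" & res$id_j == "SNP2copy", ]
  single <- scan_single_marker(pp$y, pp$G, K, markers = "SNP2")
  expect_equal(row$p, single$p, tolerance = 1e-9)
})

test_that("the proxy marker tops the marginal scan but dies when conditioned away", {
  # single-replicate demonstration of the ghost-association mechanism; the
  # replicated rates live in the acceptance suite
  pp <- planted_panel(7, n_lines = 200, n_markers = 2000)
  K <- estimate_kinship(pp$G)
  reg_ids <- pp$G$map$id[markers_in_region(pp$G, pp$region)]
  res <- scan_single_marker(pp$y, pp$G, K)
  reg <- res[res$id %in% reg_ids, ]
  expect_equal(reg$id[which.min(reg$p)], "SNP1")
  thr <- bonferroni_threshold(0.05, nrow(res))
  expect_lt(reg$p[reg$id == "SNP1"], thr)
  cond <- scan_single_marker(pp$y, pp$G, K,
                             X = pp$G$dosage[, c("SNP2", "SNP3")],
                             markers = "SNP1")
  expect_gt(cond$p, thr)
})

test_that("MLMM forces the start marker, steps by one, and partitions variance", {
  pp <- planted_panel(103, n_lines = 150, n_markers = 400,
                      n_region_markers = 20)
  K <- estimate_kinship(pp$G)
  path <- mlmm(pp$y, pp$G, K, start_marker = "SNP3", max_forward = 3)
  st <- path$steps
  expect_equal(st$cofactors[2], "SNP3")  # forced in at step 1
  expect_equal(st$direction, c("null", rep("forward", 3), rep("backward", 3)))
  expect_equal(st$n_cofactors, c(0, 1, 2, 3, 2, 1, 0))
  expect_equal(st$explained + st$genetic + st$error, rep(1, 7),
               tolerance = 1e-9)
  expect_equal(variance_explained(path, 0), 0)
  expect_error(mlmm(pp$y, pp$G, K, max_forward = 80), "n/2")
  expect_error(mlmm(pp$y, pp$G, K, start_marker = "nope"), "start_marker")
})

test_that("null-step extBIC equals -2 times the maximized ML likelihood", {
  set.seed(9)
  n <- 30
  Z <- matrix(rbinom(n * 60, 1, 0.5), n)
  G <- tiny_G(Z[, 1:10], chrom = "1")
  K <- estimate_kinship(Z)
  y <- draw_mvn_pheno(K, 1, 1)
  path <- mlmm(y, G, K, max_forward = 2)
  grid <- 10^seq(-5, 5, length.out = 1000)
  ml <- max(vapply(grid, function(d) ml_loglik_direct(d, y, K), numeric(1)))
  expect_equal(path$steps$extBIC[1], -2 * ml, tolerance = 1e-3)
})

test_that("variance explained approaches its generative share", {
  # marker contributing ~50% of phenotypic variance
  set.seed(10)
  n <- 500
  Z <- matrix(rbinom(n * 300, 1, 0.5), n)
  G <- tiny_G(Z[, 1:50], chrom = "1")
  K <- estimate_kinship(Z)
  g <- Z[, 7]
  beta <- sqrt(1 / var(g))
  y <- g * beta + rnorm(n)
  path <- mlmm(y, G, K, max_forward = 2)
  step_with <- which(vapply(strsplit(path$steps$cofactors, "+", fixed = TRUE),
                            function(cf) "m07" %in% cf, logical(1)))[1] - 1
  expect_lt(abs(variance_explained(path, step_with) - 0.5), 0.07)
  # a noise-free self-cofactor explains everything
  G2 <- tiny_G(cbind(y, Z[, 60]), chrom = "1")
  path2 <- mlmm(y, G2, K, start_marker = "m01", max_forward = 1)
  expect_gt(variance_explained(path2, 1), 0.95)
})

test_that("haplogroup calls follow the three-SNP truth table", {
  d <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, 0, 1), c(NA, 0, 0))
  G <- tiny_G(d, chrom = "5", pos = c(18592365, 18591702, 18590289),
              ids = c("SNP2", "SNP3", "SNP4"))
  calls <- assign_haplogroups(G)
  expect_equal(calls$haplogroup,
               c("ND", "D2", "D3", "D4", "ambiguous", "ambiguous",
                 "ambiguous"))
  expect_error(assign_haplogroups(tiny_G(d[, 1:2], chrom = "5")),
               "must be present")
})
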