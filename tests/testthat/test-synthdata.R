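# Synthetic-data generator: structure, locus planting, phenotype, crosses
# and field cohorts, against closed-form and brute-force oracles.

test_that("generator config validation rejects invalid parameters", {
  expect_error(population_config(n_lines = 1), "n_lines")
  expect_error(population_config(fst = 1), "fst")
  expect_error(population_config(n_markers = 0), "n_markers")
  expect_error(population_config(n_markers = 10, n_region_markers = 20),
               "n_region_markers")
  expect_error(locus_spec(haplogroup_freqs = c(ND = 0.6, D2 = 0.3,
                                               D3 = 0.2, D4 = 0)),
               "sum to 1")
})

test_that("every generator operation is reproducible given its seed", {
  pc <- population_config(n_lines = 60, n_markers = 300, seed = 11)
  G1 <- simulate_structured_genotypes(pc)
  G2 <- simulate_structured_genotypes(pc)
  expect_identical(G1$dosage, G2$dosage)
  expect_identical(G1$map, G2$map)
  spec <- locus_spec()
  P1 <- plant_heterogeneity_locus(G1, spec, seed = 3)
  P2 <- plant_heterogeneity_locus(G2, spec, seed = 3)
  expect_identical(P1$dosage, P2$dosage)
  expect_identical(simulate_phenotype(P1, spec, seed = 4),
                   simulate_phenotype(P2, spec, seed = 4))
  pool1 <- simulate_f3_pool(c(1, 1, 0, 2), 0.8, 5, seed = 6)
  pool2 <- simulate_f3_pool(c(1, 1, 0, 2), 0.8, 5, seed = 6)
  expect_identical(pool1, pool2)
})

test_that("population structure follows the FST knob, matching direct allele sharing", {
  # FST = 0.3: within-subpopulation kinship must exceed between, and the
  # centered-IBS gap must agree in direction with raw allele-sharing means
  pc <- population_config(n_lines = 200, n_markers = 2000, n_subpops = 2,
                          fst = 0.3, n_region_markers = 0, seed = 21)
  G <- simulate_structured_genotypes(pc)
  K <- estimate_kinship(G)
  sub <- G$lines$subpop
  same <- outer(sub, sub, "==")
  lower <- lower.tri(K)
  gap_K <- mean(K[lower & same]) - mean(K[lower & !same])
  # brute-force oracle: average proportion of shared dosages
  S <- 1 - as.matrix(stats::dist(G$dosage, method = "manhattan")) /
    ncol(G$dosage)
  gap_S <- mean(S[lower & same]) - mean(S[lower & !same])
  expect_gt(gap_K, 0.1)
  expect_gt(gap_S, 0.02)
  expect_gt(cor(K[lower], S[lower]), 0.8)

  # FST = 0 limit: the gap collapses to sampling noise
  pc0 <- population_config(n_lines = 200, n_markers = 2000, n_subpops = 2,
                           fst = 0, n_region_markers = 0, seed = 22)
  K0 <- estimate_kinship(simulate_structured_genotypes(pc0))
  gap0 <- mean(K0[lower & same]) - mean(K0[lower & !same])
  expect_lt(abs(gap0), 0.05)
})

test_that("planted dormant alleles are mutually exclusive across lines", {
  for (seed in c(1, 2, 3)) {
    pp <- planted_panel(seed, n_lines = 150, n_markers = 400)
    tags <- pp$G$dosage[, c("SNP2", "SNP3", "SNP4")]
    expect_true(all(rowSums(tags) <= 1))
    hap <- pp$G$lines$haplogroup
    expect_identical(unname(tags[, "SNP2"]), as.integer(hap == "D2"))
    expect_identical(unname(tags[, "SNP4"]), as.integer(hap == "D4"))
  }
})

test_that("noise-free proxy equals the OR of SNP2 and SNP3 exactly", {
  spec <- locus_spec(proxy_r2 = NULL)
  pp <- planted_panel(31, n_lines = 100, n_markers = 300, spec = spec)
  d <- pp$G$dosage
  expect_identical(unname(d[, "SNP1"]),
                   as.integer(d[, "SNP2"] | d[, "SNP3"]))
  expect_equal(ld_r2(d[, "SNP1"], as.integer(d[, "SNP2"] | d[, "SNP3"])), 1)
})

test_that("an all-ND locus is monomorphic with MAF zero downstream", {
  spec <- locus_spec(haplogroup_freqs = c(ND = 1, D2 = 0, D3 = 0, D4 = 0),
                     proxy_r2 = NULL)
  pp <- planted_panel(32, n_lines = 80, n_markers = 300, spec = spec)
  expect_equal(unname(marker_maf(pp$G$dosage[, c("SNP1", "SNP2", "SNP3",
                                                 "SNP4")])),
               c(0, 0, 0, 0))
  # with a target r-squared the calibration cannot proceed at all
  expect_error(plant_heterogeneity_locus(
    simulate_structured_genotypes(population_config(n_lines = 80,
                                                    n_markers = 300,
                                                    seed = 33)),
    locus_spec(haplogroup_freqs = c(ND = 1, D2 = 0, D3 = 0, D4 = 0)),
    seed = 1), "monomorphic")
})

test_that("proxy calibration lands within 0.1 of the target r-squared", {
  for (seed in c(41, 42, 43)) {
    pp <- planted_panel(seed, n_lines = 200, n_markers = 500)
    d <- pp$G$dosage
    realized <- ld_r2(d[, "SNP1"], d[, "SNP2"])
    expect_gte(realized, 0.51)
    expect_lte(realized, 0.71)
    expect_equal(attr(pp$G, "realized_proxy_r2"), realized)
  }
})

test_that("phenotype is a bounded logistic of liability, constant at 50 when flat", {
  spec0 <- locus_spec(effects = c(SNP2 = 0, SNP3 = 0, SNP4 = 0),
                      baseline = 0, proxy_r2 = NULL)
  pp <- planted_panel(51, n_lines = 60, n_markers = 200, spec = spec0)
  y <- simulate_phenotype(pp$G, spec0, h2_background = 0, noise_sd = 0,
                          seed = 1)
  expect_equal(as.vector(y), rep(50, 60))
  # bounds hold under extreme parameters
  spec_big <- locus_spec(effects = c(SNP2 = -60, SNP3 = 40, SNP4 = -100),
                         baseline = 30, proxy_r2 = NULL)
  y2 <- simulate_phenotype(pp$G, spec_big, h2_background = 0.9,
                           noise_sd = 25, seed = 2)
  expect_true(all(y2 >= 0 & y2 <= 100))
})

test_that("large dormant effects produce the expected bimodal mass at n = 10,000", {
  # oracle: the generative model itself at large n, no polygenic term
  spec <- locus_spec(baseline = 3, proxy_r2 = NULL)
  pc <- population_config(n_lines = 10000, n_markers = 10,
                          n_region_markers = 10, seed = 61)
  G <- simulate_structured_genotypes(pc)
  G <- plant_heterogeneity_locus(G, spec, seed = 62)
  y <- simulate_phenotype(G, spec, h2_background = 0, noise_sd = 1.8,
                          seed = 63)
  expect_gte(mean(y < 20) + mean(y > 80), 0.4)
})

test_that("F2 genotypes follow Mendelian segregation and chromosome independence", {
  map <- data.frame(id = c("a1", "a2", "a3", "b1"),
                    chrom = c("1", "1", "1", "2"),
                    pos = c(1e6, 6e6, 25e6, 5e6))
  f2 <- simulate_f2(c(0, 0, 0, 0), c(1, 1, 1, 1), 2000, map, seed = 71)
  for (j in 1:4) {
    frac <- tabulate(f2$dosage[, j] + 1, 3) / 2000
    se3 <- 3 * sqrt(c(.25, .5, .25) * c(.75, .5, .75) / 2000)
    expect_true(all(abs(frac - c(0.25, 0.5, 0.25)) < se3))
  }
  # markers on different chromosomes segregate independently
  expect_lt(abs(cor(f2$dosage[, "a1"], f2$dosage[, "b1"])), 3 / sqrt(2000))
  # tightly linked markers correlate near 1 - 2c (c from Haldane at ~0.21 M)
  expect_gt(cor(f2$dosage[, "a1"], f2$dosage[, "a2"]), 0.4)
  # identical parents give a monomorphic table
  f2m <- simulate_f2(c(1, 0, 1, 0), c(1, 0, 1, 0), 50, map, seed = 72)
  expect_identical(unique(as.vector(f2m$dosage[, 1])), 2L)
  expect_identical(unique(as.vector(f2m$dosage[, 2])), 0L)
  expect_error(simulate_f2(c(0.5, 0, 1, 0), c(1, 0, 1, 0), 10, map),
               "homozygous")
})

test_that("F3 pools have exact sizes and Mendelian selfing fractions", {
  pool <- simulate_f3_pool(c(0, 1, 2), 1, 7, seed = 81)
  expect_equal(nrow(pool), 21)
  expect_error(simulate_f3_pool(integer(0), 1, 5), "family")
  big <- simulate_f3_pool(1L, 1, 20000, seed = 82)
  frac <- tabulate(big$genotype + 1, 3) / 20000
  se3 <- 3 * sqrt(c(.25, .5, .25) * c(.75, .5, .75) / 20000)
  expect_true(all(abs(frac - c(0.25, 0.5, 0.25)) < se3))
  expect_true(all(big$viable))
})

test_that("field cohort conserves seeds exactly and matches its closed-form truth", {
  pool <- simulate_f3_pool(rep(1L, 20000), 1, 5, seed = 91)  # 100,000 seeds
  des <- field_design(n_blocks = 1, frames_per_block = 1, seed = 92)
  coh <- simulate_field_cohort(pool, des)
  f <- coh$fates[[1]]
  # conservation: germinated-by-1 + by-2 + bank + died = viable, per genotype
  expect_equal(unname(f[, "germ1"] + f[, "germ2"] + f[, "bank"] +
                        f[, "died_ungerm"]),
               unname(f[, "viable"]))
  # empirical ending frequencies vs the closed-form TruthRecord
  live <- f[, "gc1"] + f[, "gc2"] + f[, "bank"]
  emp <- live / sum(live)
  se3 <- 3 * sqrt(coh$truth$end * (1 - coh$truth$end) / sum(live))
  expect_true(all(abs(emp - coh$truth$end) < se3))
})

test_that("genotype-independent cohorts imply unit relative fitness", {
  gm <- rbind(DD = c(0.4, 0.3, 0.2), DN = c(0.4, 0.3, 0.2),
              NN = c(0.4, 0.3, 0.2))
  colnames(gm) <- c("germ1", "germ2", "bank")
  sm <- rbind(DD = c(0.5, 0.6), DN = c(0.5, 0.6), NN = c(0.5, 0.6))
  colnames(sm) <- c("surv1", "surv2")
  des <- field_design(germination_model = gm, survival_model = sm, seed = 93)
  pool <- simulate_f3_pool(rep(1L, 500), 1, 5, seed = 94)
  coh <- simulate_field_cohort(pool, des)
  expect_equal(unname(coh$truth$relative_fitness), c(1, 1, 1))
  expect_equal(unname(coh$truth$end), unname(coh$truth$start))
})

test_that("full soil sampling with no movement recovers the entire seed bank", {
  des <- field_design(n_blocks = 1, frames_per_block = 2,
                      soil_sampled_cm2 = 600, frame_area_cm2 = 600,
                      moved_prob = 0, seed = 95)
  pool <- simulate_f3_pool(rep(1L, 400), 1, 5, seed = 96)
  coh <- simulate_field_cohort(pool, des)
  f <- coh$fates[[1]]
  expect_equal(unname(f[, "gc3"]), unname(f[, "bank"]))
  expect_equal(sum(f[, c("out1", "out2")]), 0)
})

test_that("field design validation enforces probability and area constraints", {
  gm <- rbind(DD = c(0.6, 0.5, 0.2), DN = c(0.3, 0.3, 0.2),
              NN = c(0.3, 0.3, 0.2))
  colnames(gm) <- c("germ1", "germ2", "bank")
  expect_error(field_design(germination_model = gm), "<= 1")
  expect_error(field_design(soil_sampled_cm2 = 700), "frame_area")
  expect_error(field_design(moved_prob = 1.2), "moved_prob")
})
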