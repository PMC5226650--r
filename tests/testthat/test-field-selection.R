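# Field-selection estimators: Mendelian starting frequencies, movement and
# area corrections, fitness arithmetic, window calls, and recovery of
# simulated selection differentials.

test_that("starting frequencies apply viability-weighted Mendelian selfing", {
  expect_equal(as.numeric(starting_frequencies(1L, 1, 5)),
               c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(as.numeric(starting_frequencies(c(2L, 0L), c(1, 1), 4)),
               c(0.5, 0, 0.5), tolerance = 1e-12)
  # hand-weighted oracle: {DD v=1, DN v=0.5}, equal seeds ->
  # weights (1, 0.5); freqs = (1 + .5*.25, .5*.5, .5*.25)/1.5
  f <- starting_frequencies(c("DD", "DN"), c(1, 0.5), 1)
  expect_equal(as.numeric(f), c(0.75, 1 / 6, 1 / 12), tolerance = 1e-12)
  expect_equal(attr(f, "p_allele"), 0.75 + 1 / 12, tolerance = 1e-12)
  expect_error(starting_frequencies(c(1L, 1L), c(0, 0)), "zero")
  expect_error(starting_frequencies(1L, 1.4), "\\[0, 1\\]")
})

test_that("moved fraction is outside over total with guarded edges", {
  expect_equal(estimate_moved(0, 40), 0)
  expect_equal(estimate_moved(2, 40), 0.05)
  expect_equal(estimate_moved(5, 94), 5 / 94)
  expect_error(estimate_moved(1, 0), "positive")
  expect_error(estimate_moved(5, 4), "outside_count")
})

test_that("CEGC combines seedling and scaled soil counts exactly", {
  expect_equal(ending_genotype_counts(c(3, 1, 2), c(4, 0, 1), c(0, 0, 0),
                                      area = 100 / 3, moved = 0.05),
               c(7, 1, 3))
  expect_equal(ending_genotype_counts(c(10, 0, 0), c(5, 0, 0), c(3, 0, 0),
                                      area = 100 / 3, moved = 0),
               c(115, 0, 0))
  expect_equal(ending_genotype_counts(c(10, 0, 0), c(5, 0, 0), c(3, 0, 0),
                                      area = 100 / 3, moved = 0.053)[1],
               120.3, tolerance = 1e-9)
  expect_error(ending_genotype_counts(c(-1, 0, 0), c(0, 0, 0), c(0, 0, 0)),
               "nonnegative")
  expect_error(ending_genotype_counts(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0),
                                      area = 0.5), "area")
})

test_that("fitness arithmetic follows w = (end/start) * mean fitness", {
  eq <- frequency_set(0.25, 0.5, 0.25)
  ft <- fitness_estimates(eq, eq, 1)
  expect_equal(ft$marginal, c(1, 1, 1))
  expect_equal(ft$relative, c(1, 1, 1))
  ft2 <- fitness_estimates(c(0.25, 0.5, 0.25), c(0.5, 0.3, 0.2), 0.4)
  expect_equal(ft2$marginal[1], 0.8)
  expect_equal(ft2$relative[1], 1)
  expect_error(fitness_estimates(c(0, 0.5, 0.5), c(0.2, 0.4, 0.4), 0.5),
               "absent at the start")
  # unstable heterozygote estimates are flagged
  ft3 <- fitness_estimates(c(0.95, 0.01, 0.04), c(0.9, 0.02, 0.08), 0.5)
  expect_true(ft3$low_confidence[2])
  expect_error(frequency_set(0.5, 0.4, 0.4), "sum to 1")
})

test_that("block aggregation pools inside and outside seedlings but not soil", {
  counts <- data.frame(
    population = "p", block = 1,
    sampling_point = c(1, 1, 2, 2, 3, 1),
    genotype = c("DD", "DD", "DD", "NN", "DN", "NN"),
    count = c(5, 2, 3, 4, 6, 1),
    location = c("inside", "outside", "inside", "outside", "soil", "inside"))
  sc <- collect_sampling_counts(counts, "p", 1)
  expect_equal(unname(sc$gc1), c(7, 0, 1))
  expect_equal(unname(sc$gc2), c(3, 0, 4))
  expect_equal(unname(sc$gc3), c(0, 6, 0))
  expect_equal(sc$outside, 6)
  expect_equal(sc$total_seedlings, 15)
})

test_that("the estimator recovers simulated selection across a differential grid", {
  gm <- rbind(DD = c(0.4, 0.3, 0.2), DN = c(0.4, 0.3, 0.2),
              NN = c(0.4, 0.3, 0.2))
  colnames(gm) <- c("germ1", "germ2", "bank")
  pool <- simulate_f3_pool(rep(1L, 10000), 1, 5, seed = 171)  # 50,000 seeds
  for (s in c(0, 0.2, 0.4, 0.6)) {
    sm <- rbind(DD = c(0.6, 0.7), DN = c(0.6, 0.7) * (1 - s / 2),
                NN = c(0.6, 0.7) * (1 - s))
    colnames(sm) <- c("surv1", "surv2")
    ests <- vapply(1:10, function(i) {
      des <- field_design(n_blocks = 1, frames_per_block = 1,
                          germination_model = gm, survival_model = sm,
                          moved_prob = 0.04, seed = 180 + 20 * s + i)
      coh <- simulate_field_cohort(pool, des)
      ft <- estimate_field_fitness(coh$counts, coh$truth$start,
                                   coh$truth$mean_fitness, block = 1)
      ft$relative[ft$genotype == "NN"]
    }, numeric(1))
    truth_des <- field_design(germination_model = gm, survival_model = sm)
    truth <- simulate_field_cohort(pool, truth_des)$truth
    expect_lt(abs(median(ests) - truth$relative_fitness[["NN"]]), 0.05)
  }
})

test_that("window calls threshold the polarized allele fraction with a depth guard", {
  expect_equal(window_genotype_call(20, 0), "hom_A")
  expect_equal(window_genotype_call(0, 20), "hom_B")
  expect_equal(window_genotype_call(11, 9), "het")
  expect_equal(window_genotype_call(4, 1, min_informative = 10), "missing")
  expect_equal(window_genotype_call(8, 2, min_informative = 5), "missing")
  expect_equal(window_genotype_call(c(18, 0, 5), c(2, 20, 5)),
               c("hom_A", "hom_B", "het"))
})

test_that("genotyping windows tile half-open intervals from position 1", {
  w <- tile_windows(c(chr1 = 450000, chr2 = 200000), size = 200000)
  expect_equal(w$start[w$chrom == "chr1"], c(1, 200001, 400001))
  expect_equal(w$end - w$start, rep(200000, nrow(w)))
  # non-overlapping, exhaustive cover
  expect_true(all(diff(w$start[w$chrom == "chr1"]) == 200000))
})
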