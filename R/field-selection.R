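# Field-experiment estimators: viability-weighted starting frequencies,
# movement- and area-corrected ending genotype counts (CEGC), and
# marginal/relative fitnesses per genotype.

#' Genotype frequency triple
#'
#' @param pp,pq,qq frequencies of the dormant homozygote, heterozygote and
#'   non-dormant homozygote; must be nonnegative and sum to 1.
#' @return named numeric vector of class `frequency_set`; the dormant-allele
#'   frequency `pp + pq/2` is attached as `attr(, "p_allele")`.
#' @export
frequency_set <- function(pp, pq, qq) {
  f <- c(pp = unname(pp), pq = unname(pq), qq = unname(qq))
  if (any(f < -1e-12) || abs(sum(f) - 1) > 1e-9) {
    stop("genotype frequencies must be nonnegative and sum to 1",
         call. = FALSE)
  }
  structure(pmax(f, 0), p_allele = unname(f[["pp"]] + f[["pq"]] / 2),
            class = "frequency_set")
}

#' Starting genotype frequencies from F2 families and seed viability
#'
#' Each family contributes `seeds_per_family * viability` viable-seed
#' weight, split across offspring genotypes by Mendelian selfing
#' (homozygote breeds true; heterozygote gives 1/4, 1/2, 1/4); weights are
#' normalized to frequencies.
#'
#' @param f2_genotypes per-family F2 genotype at the focal locus, coded
#'   0/1/2 (dormant-allele count) or `"NN"/"DN"/"DD"`.
#' @param viability per-family viable fraction in \[0, 1\] (recycled).
#' @param seeds_per_family seeds contributed per family (recycled).
#' @return a [frequency_set()] (pp = DD, pq = DN, qq = NN).
#' @export
starting_frequencies <- function(f2_genotypes, viability,
                                 seeds_per_family = 1) {
  if (is.character(f2_genotypes) || is.factor(f2_genotypes)) {
    g <- match(as.character(f2_genotypes), GENO_LEVELS) # DD=1, DN=2, NN=3
    if (anyNA(g)) stop("genotypes must be DD, DN or NN", call. = FALSE)
    g <- 3 - g  # to dormant-allele count
  } else {
    g <- as.integer(f2_genotypes)
    stopifnot(all(g %in% 0:2))
  }
  n_fam <- length(g)
  viability <- rep_len(viability, n_fam)
  if (any(viability < 0 | viability > 1)) {
    stop("viabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!any(viability > 0)) {
    stop("total viable-seed weight is zero", call. = FALSE)
  }
  seeds <- rep_len(seeds_per_family, n_fam)
  w <- viability * seeds
  selfing <- rbind(`0` = c(0, 0, 1),    # NN  -> all NN
                   `1` = c(0.25, 0.5, 0.25),  # DN -> 1/4 DD, 1/2 DN, 1/4 NN
                   `2` = c(1, 0, 0))    # DD -> all DD
  contrib <- selfing[as.character(g), , drop = FALSE] * w
  f <- colSums(contrib) / sum(w)
  frequency_set(f[1], f[2], f[3])
}

#' Proportion of seeds moved outside the frames
#'
#' Outside-frame seedlings at sampling points 1 and 2, divided by all
#' seedlings collected at both points.
#'
#' @param outside_count seedlings found outside the frames.
#' @param total_count all seedlings collected (inside + outside).
#' @return fraction `outside_count / total_count`.
#' @export
estimate_moved <- function(outside_count, total_count) {
  if (total_count <= 0) stop("total_count must be positive", call. = FALSE)
  if (outside_count < 0 || outside_count > total_count) {
    stop("need 0 <= outside_count <= total_count", call. = FALSE)
  }
  outside_count / total_count
}

#' Corrected ending genotype counts (CEGC)
#'
#' `CEGC = GC1 + GC2 + GC3 * area * (1 + moved)`, elementwise over the
#' genotype triple: September seedlings plus November seedlings plus
#' soil-sample counts scaled up by the sampling-area factor and the
#' outside-frame movement fraction.  Real-valued by construction.
#'
#' @param gc1,gc2,gc3 genotype-count triples (DD, DN, NN) for sampling
#'   points 1 (September), 2 (November) and 3 (soil).
#' @param area soil-sampling area factor (>= 1); 100/3 when 3% of the frame
#'   was sampled.
#' @param moved outside-frame movement fraction in \[0, 1).
#' @return numeric triple of corrected ending genotype counts.
#' @export
ending_genotype_counts <- function(gc1, gc2, gc3, area = 100 / 3, moved = 0) {
  stopifnot(length(gc1) == length(gc2), length(gc2) == length(gc3))
  if (any(c(gc1, gc2, gc3) < 0)) {
    stop("genotype counts must be nonnegative", call. = FALSE)
  }
  if (area < 1) stop("area factor must be >= 1", call. = FALSE)
  check_fraction(moved, "moved", 0, 1, hi_open = TRUE)
  gc1 + gc2 + gc3 * area * (1 + moved)
}

#' Marginal and relative fitnesses from frequency change
#'
#' Marginal fitness per genotype `w_g = (end_g / start_g) * mean_fitness`;
#' relative fitnesses divide by the fittest genotype's marginal fitness.
#' The heterozygote estimate is flagged low-confidence when its starting
#' frequency is below 0.05 (division instability).
#'
#' @param start,end [frequency_set()]s (or triples) of starting and ending
#'   genotype frequencies.
#' @param mean_fitness proportion of dispersed individuals alive at the end
#'   of the experiment, in (0, 1\].
#' @return data.frame of class `fitness_table` with one row per genotype
#'   (DD, DN, NN): `start`, `end`, `marginal`, `relative`, `low_confidence`;
#'   `attr(, "mean_fitness")` carries the input mean fitness.
#' @export
fitness_estimates <- function(start, end, mean_fitness) {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 3, length(end) == 3)
  check_fraction(mean_fitness, "mean_fitness", 0, 1, lo_open = TRUE)
  if (any(start == 0 & end > 0)) {
    stop("a genotype absent at the start cannot have nonzero ending ",
         "frequency", call. = FALSE)
  }
  marginal <- ifelse(start > 0, end / start * mean_fitness, 0)
  if (all(marginal == 0)) stop("all marginal fitnesses are zero",
                               call. = FALSE)
  out <- data.frame(genotype = GENO_LEVELS,
                    start = start, end = end,
                    marginal = marginal,
                    relative = marginal / max(marginal),
                    low_confidence = c(FALSE, start[2] < 0.05, FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "mean_fitness") <- mean_fitness
  class(out) <- c("fitness_table", "data.frame")
  out
}

#' Aggregate a tidy cohort count table into sampling-count triples
#'
#' Sums counts at the block level: GC1 and GC2 pool inside and outside
#' seedlings at sampling points 1 and 2; GC3 is the soil-sample count.
#'
#' @param counts tidy data.frame with columns `population`, `block`,
#'   `sampling_point`, `genotype`, `count`, `location` (as emitted by
#'   [simulate_field_cohort()] or read from CSV).
#' @param population,block the stratum to aggregate.
#' @return list of class `sampling_counts`: `gc1`, `gc2`, `gc3` (genotype
#'   triples DD/DN/NN), `outside` and `total_seedlings` at points 1-2.
#' @export
collect_sampling_counts <- function(counts, population = counts$population[1],
                                    block = 1) {
  d <- counts[counts$population == population & counts$block == block, ]
  if (nrow(d) == 0) stop("no counts for that population/block", call. = FALSE)
  tri <- function(sub) {
    out <- vapply(GENO_LEVELS, function(g) sum(sub$count[sub$genotype == g]),
                  numeric(1))
    out
  }
  s12 <- d[d$sampling_point %in% c(1, 2) & d$location != "soil", ]
  structure(list(
    gc1 = tri(d[d$sampling_point == 1 & d$location != "soil", ]),
    gc2 = tri(d[d$sampling_point == 2 & d$location != "soil", ]),
    gc3 = tri(d[d$sampling_point == 3 | d$location == "soil", ]),
    outside = sum(s12$count[s12$location == "outside"]),
    total_seedlings = sum(s12$count)),
    class = "sampling_counts")
}

#' End-to-end fitness estimation for one population x block
#'
#' Runs the full estimator chain on a tidy count table: movement fraction
#' from outside-frame seedlings, CEGC with the area factor, ending
#' frequencies, and marginal/relative fitnesses against the given starting
#' frequencies.
#'
#' @param counts tidy cohort count table (see [collect_sampling_counts()]).
#' @param start starting [frequency_set()].
#' @param mean_fitness mean fitness (proportion alive at the end).
#' @param population,block stratum selectors.
#' @param area soil-sampling area factor.
#' @return a `fitness_table` (see [fitness_estimates()]) with the estimated
#'   `moved` fraction and ending frequencies in attributes.
#' @export
estimate_field_fitness <- function(counts, start, mean_fitness,
                                   population = counts$population[1],
                                   block = 1, area = 100 / 3) {
  sc <- collect_sampling_counts(counts, population, block)
  moved <- if (sc$total_seedlings > 0) {
    estimate_moved(sc$outside, sc$total_seedlings)
  } else 0
  cegc <- ending_genotype_counts(sc$gc1, sc$gc2, sc$gc3, area, moved)
  if (sum(cegc) == 0) stop("no individuals recovered", call. = FALSE)
  end <- frequency_set(cegc[1] / sum(cegc), cegc[2] / sum(cegc),
                       cegc[3] / sum(cegc))
  ft <- fitness_estimates(start, end, mean_fitness)
  attr(ft, "moved") <- moved
  attr(ft, "end") <- end
  ft
}

#' Window genotype call from polarized allele counts
#'
#' For a window's read-backed SNP calls polarized to the two parents, the
#' parent-A allele fraction `f = n_A / (n_A + n_B)` is thresholded:
#' `hom_A` if f >= 0.9, `hom_B` if f <= 0.1, `het` if 0.3 <= f <= 0.7,
#' otherwise `missing`; windows with fewer than `min_informative` calls are
#' `missing`.
#'
#' @param n_a,n_b informative allele counts for parents A and B (vectors).
#' @param min_informative minimum calls per window.
#' @return character vector in `{"hom_A", "het", "hom_B", "missing"}`.
#' @export
window_genotype_call <- function(n_a, n_b, min_informative = 10) {
  stopifnot(length(n_a) == length(n_b), all(n_a >= 0), all(n_b >= 0))
  tot <- n_a + n_b
  f <- ifelse(tot > 0, n_a / tot, NA_real_)
  out <- rep("missing", length(f))
  out[!is.na(f) & f >= 0.9] <- "hom_A"
  out[!is.na(f) & f <= 0.1] <- "hom_B"
  out[!is.na(f) & f >= 0.3 & f <= 0.7] <- "het"
  out[tot < min_informative] <- "missing"
  out
}

#' Tile non-overlapping genotyping windows along chromosomes
#'
#' Windows are 1-based, half-open `[start, start + size)`, tiled from
#' position 1 on each chromosome.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param size window size in bp (default 200 kb).
#' @return data.frame with `chrom`, `start`, `end` (half-open).
#' @export
tile_windows <- function(chrom_lengths, size = 200000) {
  size <- check_count(size, "size")
  out <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1, chrom_lengths[[ch]], by = size)
    data.frame(chrom = ch, start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
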