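# Synthetic-data generator: structured inbred panels, a heterogeneous
# dormancy locus with a calibrated proxy marker, bimodal germination
# phenotypes, F2/F3 crosses and staged field cohorts with closed-form truth.

SNP_POSITIONS <- c(SNP1 = 18570773, SNP2 = 18592365,
                   SNP3 = 18591702, SNP4 = 18590289)
GENO_LEVELS <- c("DD", "DN", "NN")  # dormant-allele count 2, 1, 0

#' Configuration of a structured inbred panel
#'
#' Parameters of the Balding-Nichols simulation of a panel of inbred lines
#' with background population structure.  Defaults emulate a Swedish
#' *A. thaliana* accession panel: 161 lines split between a southern and a
#' northern subpopulation with moderate differentiation.
#'
#' @param n_lines number of inbred lines (>= 2).
#' @param n_markers total number of biallelic markers, including the
#'   `n_region_markers` placed densely inside `region`.
#' @param n_subpops number of subpopulations.
#' @param fst Wright's FST in \[0, 1) controlling drift of subpopulation
#'   allele frequencies around the ancestral frequency.
#' @param n_region_markers markers placed uniformly inside `region` to give
#'   the candidate region a realistic local SNP density.
#' @param region the candidate region (see [parse_region()]); default is a
#'   50 kb window on chromosome 5 containing the dormancy locus.
#' @param seed integer root seed.
#' @return list of class `population_config`.
#' @export
population_config <- function(n_lines = 161, n_markers = 2000,
                              n_subpops = 2, fst = 0.1,
                              n_region_markers = 60,
                              region = "5:18560000-18610000",
                              seed = 1) {
  n_lines <- check_count(n_lines, "n_lines", min = 2)
  n_markers <- check_count(n_markers, "n_markers", min = 1)
  n_subpops <- check_count(n_subpops, "n_subpops", min = 1)
  n_region_markers <- check_count(n_region_markers, "n_region_markers",
                                  min = 0)
  if (n_region_markers > n_markers) {
    stop("n_region_markers cannot exceed n_markers", call. = FALSE)
  }
  check_fraction(fst, "fst", 0, 1, hi_open = TRUE)
  structure(list(n_lines = n_lines, n_markers = n_markers,
                 n_subpops = n_subpops, fst = fst,
                 n_region_markers = n_region_markers,
                 region = parse_region(region), seed = seed),
            class = "population_config")
}

#' Specification of the heterogeneous dormancy locus
#'
#' Four haplogroups segregate at the locus: ND (non-dormant, early alleles
#' everywhere) and three dormant classes D2, D3, D4 tagged by mutually
#' exclusive late alleles at SNP2, SNP3 and SNP4.  A proxy marker SNP1,
#' 21 kb from the locus, carries (approximately) the logical OR of SNP2 and
#' SNP3, with calibrated noise so that r-squared(SNP1, SNP2) hits a target.
#'
#' Effects are on the liability scale of [simulate_phenotype()]; `baseline`
#' is the liability of an ND line.  Defaults were chosen to emulate the
#' observed germination-rate distribution (about 46% of lines deeply
#' dormant and 35% effectively non-dormant).
#'
#' @param region region containing the locus and proxy positions.
#' @param effects named liability effects of the dormant alleles.
#' @param baseline ND liability baseline.
#' @param haplogroup_freqs named frequencies of ND, D2, D3, D4; must sum
#'   to 1.
#' @param proxy_r2 target r-squared between SNP1 and SNP2; `NULL` for a
#'   noise-free proxy (SNP1 = OR(SNP2, SNP3) exactly); `NA` to plant no
#'   proxy marker at all.
#' @return list of class `locus_spec`.
#' @export
locus_spec <- function(region = "5:18560000-18610000",
                       effects = c(SNP2 = -6, SNP3 = -6, SNP4 = -6),
                       baseline = 2.5,
                       haplogroup_freqs = c(ND = 0.50, D2 = 0.30,
                                            D3 = 0.18, D4 = 0.02),
                       proxy_r2 = 0.61) {
  region <- parse_region(region)
  stopifnot(all(names(effects) %in% c("SNP2", "SNP3", "SNP4")))
  f <- haplogroup_freqs[c("ND", "D2", "D3", "D4")]
  if (anyNA(f) || any(f < 0) || abs(sum(f) - 1) > 1e-12) {
    stop("haplogroup_freqs must name ND, D2, D3, D4 and sum to 1",
         call. = FALSE)
  }
  if (!is.null(proxy_r2) && !is.na(proxy_r2)) {
    check_fraction(proxy_r2, "proxy_r2", 0, 1)
  }
  for (s in names(SNP_POSITIONS)) {
    if (SNP_POSITIONS[[s]] < region$start || SNP_POSITIONS[[s]] > region$end) {
      stop("region must contain the canonical SNP1-SNP4 positions",
           call. = FALSE)
    }
  }
  structure(list(region = region, effects = effects, baseline = baseline,
                 haplogroup_freqs = f, proxy_r2 = proxy_r2),
            class = "locus_spec")
}

#' Simulate a structured panel of inbred lines
#'
#' Balding-Nichols scheme: ancestral allele frequencies are Uniform(0.05,
#' 0.95); each subpopulation draws its frequency from
#' Beta(p(1-FST)/FST, (1-p)(1-FST)/FST) (degenerating to p at FST = 0); each
#' inbred line then draws one Bernoulli dosage per marker.  Lines are split
#' evenly across subpopulations and given latitudes in southern
#' (55.3-58 deg N) or northern (62-66 deg N) bands.
#'
#' @param cfg a [population_config()].
#' @return a [genotype_matrix()]; `$lines` records subpopulation and
#'   latitude.  Deterministic given `cfg$seed`.
#' @export
simulate_structured_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "population_config"))
  with_seed(cfg$seed, {
    m <- cfg$n_markers
    n <- cfg$n_lines
    m_bg <- m - cfg$n_region_markers
    # marker map: background markers over 5 chromosomes, dense block in region
    chrom_bg <- as.character(rep_len(1:5, m_bg))
    pos_bg <- integer(m_bg)
    for (ch in unique(chrom_bg)) {
      idx <- which(chrom_bg == ch)
      pos_bg[idx] <- sort(sample.int(30e6, length(idx)))
    }
    reg <- cfg$region
    map <- data.frame(
      id = character(0), chrom = character(0), pos = numeric(0))
    if (m_bg > 0) {
      map <- data.frame(id = NA_character_, chrom = chrom_bg, pos = pos_bg)
    }
    if (cfg$n_region_markers > 0) {
      pos_reg <- sort(sample(seq(reg$start, reg$end),
                             cfg$n_region_markers))
      map <- rbind(map, data.frame(id = NA_character_, chrom = reg$chrom,
                                   pos = pos_reg))
    }
    ord <- order(as.integer(map$chrom), map$pos)
    map <- map[ord, , drop = FALSE]
    map$id <- sprintf("c%sp%d", map$chrom, as.integer(map$pos))
    if (anyDuplicated(map$id)) {
      keep <- !duplicated(map$id)
      map <- map[keep, , drop = FALSE]
    }
    m <- nrow(map)

    p_anc <- runif(m, 0.05, 0.95)
    subpop <- rep_len(seq_len(cfg$n_subpops), n)
    dosage <- matrix(0L, n, m)
    for (s in seq_len(cfg$n_subpops)) {
      rows <- which(subpop == s)
      p_s <- if (cfg$fst == 0) p_anc else
        rbeta(m, p_anc * (1 - cfg$fst) / cfg$fst,
              (1 - p_anc) * (1 - cfg$fst) / cfg$fst)
      dosage[rows, ] <- matrix(
        rbinom(length(rows) * m, 1L, rep(p_s, each = length(rows))),
        nrow = length(rows))
    }
    # latitudes: odd subpops south, even subpops north (two-band Sweden)
    south <- subpop %% 2 == 1
    lat <- numeric(n)
    lat[south] <- runif(sum(south), 55.3, 58.0)
    lat[!south] <- runif(sum(!south), 62.0, 66.0)
    lines <- data.frame(line_id = sprintf("line_%03d", seq_len(n)),
                        subpop = subpop, latitude = round(lat, 4),
                        stringsAsFactors = FALSE)
    rownames(dosage) <- lines$line_id
    genotype_matrix(dosage, map, lines)
  })
}

# Apply the signed proxy-noise parameter to the OR vector.
# t in [0, 1]: SNP3-only carriers lose the proxy allele w.p. t (raises
# r2 with SNP2 toward 1).  t in [-0.5, 0): uniform flips w.p. |t| (lowers it).
apply_proxy_noise <- function(or_vec, d3_only, t, u) {
  s <- or_vec
  if (t >= 0) {
    s[d3_only & u < t] <- 0L
  } else {
    fl <- u < -t
    s[fl] <- 1L - s[fl]
  }
  s
}

proxy_mean_r2 <- function(t, or_vec, d3_only, snp2, n_rep = 50) {
  r2s <- vapply(seq_len(n_rep), function(i) {
    s <- apply_proxy_noise(or_vec, d3_only, t, runif(length(or_vec)))
    if (var(s) == 0) return(0)
    cor(s, snp2)^2
  }, numeric(1))
  mean(r2s)
}

#' Plant the heterogeneous locus into a genotype matrix
#'
#' Assigns each line a haplogroup at the stated frequencies, writes the
#' mutually exclusive dormant dosages at SNP2-SNP4 (overwriting the region
#' markers nearest to the canonical positions), and writes the proxy SNP1 as
#' the logical OR of SNP2 and SNP3 with noise calibrated by bisection (50
#' calibration replicates) so the realized r-squared(SNP1, SNP2) is within
#' 0.1 of `spec$proxy_r2`.  Because symmetric flips can only lower the
#' r-squared of a pure OR, the noise is signed: it either removes the proxy
#' allele from SNP3-only carriers (raising r-squared with SNP2) or flips
#' uniformly at random (lowering it).
#'
#' @param G a [genotype_matrix()] whose map covers `spec$region`.
#' @param spec a [locus_spec()].
#' @param seed integer seed.
#' @return a modified copy of `G`; `$lines$haplogroup` records the truth and
#'   `attr(, "realized_proxy_r2")` the achieved r-squared (NA without proxy).
#' @export
plant_heterogeneity_locus <- function(G, spec, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(spec, "locus_spec"))
  reg <- spec$region
  idx_reg <- markers_in_region(G, reg)
  no_proxy <- !is.null(spec$proxy_r2) && is.na(spec$proxy_r2)
  want <- c("SNP2", "SNP3", "SNP4", if (!no_proxy) "SNP1")
  if (length(idx_reg) < length(want)) {
    stop(sprintf("region %s:%d-%d holds %d markers; need >= %d to plant the locus",
                 reg$chrom, reg$start, reg$end, length(idx_reg), length(want)),
         call. = FALSE)
  }
  with_seed(seed, {
    n <- nrow(G$dosage)
    hap <- sample(names(spec$haplogroup_freqs), n, replace = TRUE,
                  prob = spec$haplogroup_freqs)
    snp2 <- as.integer(hap == "D2")
    snp3 <- as.integer(hap == "D3")
    snp4 <- as.integer(hap == "D4")
    or_vec <- as.integer(snp2 | snp3)

    realized_r2 <- NA_real_
    if (no_proxy) {
      snp1 <- NULL
    } else if (is.null(spec$proxy_r2)) {
      snp1 <- or_vec
      if (var(snp1) > 0 && var(snp2) > 0) realized_r2 <- cor(snp1, snp2)^2
    } else {
      if (var(snp2) == 0 || var(or_vec) == 0) {
        stop("haplogroup draw left SNP2 or its OR monomorphic; ",
             "proxy calibration impossible", call. = FALSE)
      }
      d3_only <- snp3 == 1L & snp2 == 0L
      lo <- -0.5; hi <- 1
      r2_lo <- proxy_mean_r2(lo, or_vec, d3_only, snp2)
      r2_hi <- proxy_mean_r2(hi, or_vec, d3_only, snp2)
      if (spec$proxy_r2 < r2_lo - 0.1 || spec$proxy_r2 > r2_hi + 0.1) {
        stop(sprintf(paste0("target r2 %.3f unreachable for these haplogroup ",
                            "frequencies; achievable range is [%.3f, %.3f]"),
                     spec$proxy_r2, r2_lo, r2_hi), call. = FALSE)
      }
      for (i in seq_len(40)) {
        mid <- (lo + hi) / 2
        if (proxy_mean_r2(mid, or_vec, d3_only, snp2) < spec$proxy_r2) {
          lo <- mid
        } else {
          hi <- mid
        }
      }
      t_star <- (lo + hi) / 2
      snp1 <- apply_proxy_noise(or_vec, d3_only, t_star, runif(n))
      if (var(snp1) == 0) snp1 <- or_vec
      realized_r2 <- cor(snp1, snp2)^2
      if (abs(realized_r2 - spec$proxy_r2) > 0.1) {
        # one recalibration draw; small panels are noisy around the target
        snp1 <- apply_proxy_noise(or_vec, d3_only, t_star, runif(n))
        if (var(snp1) > 0) realized_r2 <- cor(snp1, snp2)^2
      }
    }

    # overwrite the region markers nearest each canonical position
    dosages <- list(SNP1 = snp1, SNP2 = snp2, SNP3 = snp3, SNP4 = snp4)
    used <- integer(0)
    for (s in c("SNP2", "SNP3", "SNP4", if (!no_proxy) "SNP1")) {
      cand <- setdiff(idx_reg, used)
      j <- cand[which.min(abs(G$map$pos[cand] - SNP_POSITIONS[[s]]))]
      used <- c(used, j)
      G$dosage[, j] <- dosages[[s]]
      G$map$id[j] <- s
      G$map$pos[j] <- SNP_POSITIONS[[s]]
    }
    ord <- order(as.integer(G$map$chrom), G$map$pos)
    G$map <- G$map[ord, , drop = FALSE]
    rownames(G$map) <- NULL
    G$dosage <- G$dosage[, ord, drop = FALSE]
    colnames(G$dosage) <- G$map$id
    G$lines$haplogroup <- hap
    attr(G, "realized_proxy_r2") <- realized_r2
    G
  })
}

#' Simulate a bimodal germination phenotype
#'
#' Liability model: L = baseline + sum of planted dormant-allele effects +
#' polygenic background + Gaussian noise, mapped to a germination rate
#' GR21 = 100 * logistic(L).  The polygenic term is multivariate normal with
#' covariance proportional to the panel kinship, scaled so its share of the
#' residual (non-locus) liability variance equals `h2_background`.
#'
#' @param G a [genotype_matrix()], normally after
#'   [plant_heterogeneity_locus()].
#' @param spec the [locus_spec()] supplying effects and baseline.
#' @param h2_background share of residual liability variance attributable to
#'   the polygenic background, in \[0, 1).
#' @param noise_sd standard deviation of the independent liability noise.
#' @param seed integer seed.
#' @return named numeric vector of GR21 values in \[0, 100\], with the
#'   latent liability in `attr(, "liability")`.
#' @export
simulate_phenotype <- function(G, spec, h2_background = 0.3, noise_sd = 1.5,
                               seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(spec, "locus_spec"))
  check_fraction(h2_background, "h2_background", 0, 1, hi_open = TRUE)
  stopifnot(noise_sd >= 0)
  with_seed(seed, {
    n <- nrow(G$dosage)
    L <- rep(spec$baseline, n)
    for (s in names(spec$effects)) {
      if (s %in% colnames(G$dosage)) {
        L <- L + spec$effects[[s]] * G$dosage[, s]
      }
    }
    sigma_p2 <- if (h2_background > 0) {
      h2_background / (1 - h2_background) * noise_sd^2
    } else 0
    if (sigma_p2 > 0) {
      K <- estimate_kinship(G)
      ch <- chol(K + diag(1e-6, n))
      L <- L + sqrt(sigma_p2) * drop(crossprod(ch, rnorm(n)))
    }
    if (noise_sd > 0) L <- L + rnorm(n, sd = noise_sd)
    gr21 <- 100 * stats::plogis(L)
    names(gr21) <- rownames(G$dosage)
    attr(gr21, "liability") <- L
    gr21
  })
}

#' Simulate an F2 intercross between two inbred parents
#'
#' Gametes are formed with Poisson-distributed crossovers per chromosome
#' (default map length one Morgan per chromosome, no interference); marker
#' genetic positions are interpolated linearly from physical positions.
#' Genotypes are allelic dosages 0/1/2 counting the second parent's allele
#' at informative markers (monomorphic where the parents agree).
#'
#' @param parentA,parentB numeric 0/1 dosage vectors over the markers of
#'   `map` (inbred, homozygous).
#' @param n number of F2 individuals.
#' @param map data.frame with `id`, `chrom`, `pos`.
#' @param seed integer seed.
#' @param morgans_per_chrom genetic length of each chromosome.
#' @return object of class `f2_genotypes`: list with `dosage` (n x m matrix)
#'   and `map`.
#' @export
simulate_f2 <- function(parentA, parentB, n, map, seed = 1,
                        morgans_per_chrom = 1) {
  n <- check_count(n, "n")
  m <- nrow(map)
  stopifnot(length(parentA) == m, length(parentB) == m)
  if (!all(parentA %in% c(0, 1)) || !all(parentB %in% c(0, 1))) {
    stop("parents must be homozygous inbred lines with 0/1 dosages",
         call. = FALSE)
  }
  with_seed(seed, {
    chroms <- unique(map$chrom)
    # genetic position of each marker within its chromosome, in Morgans
    gpos <- numeric(m)
    for (ch in chroms) {
      idx <- which(map$chrom == ch)
      p <- map$pos[idx]
      span <- max(p) - min(p)
      gpos[idx] <- if (span == 0) 0 else
        (p - min(p)) / span * morgans_per_chrom
    }
    one_gamete <- function() {
      anc <- integer(m)  # 0 = from parent A, 1 = from parent B
      for (ch in chroms) {
        idx <- which(map$chrom == ch)
        k <- rpois(1, morgans_per_chrom)
        xo <- sort(runif(k, 0, morgans_per_chrom))
        phase0 <- rbinom(1, 1, 0.5)
        n_before <- findInterval(gpos[idx], xo)
        anc[idx] <- (phase0 + n_before) %% 2
      }
      anc
    }
    dosage <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      a1 <- one_gamete(); a2 <- one_gamete()
      v1 <- ifelse(a1 == 0L, parentA, parentB)
      v2 <- ifelse(a2 == 0L, parentA, parentB)
      dosage[i, ] <- as.integer(v1 + v2)
    }
    colnames(dosage) <- map$id
    rownames(dosage) <- sprintf("f2_%04d", seq_len(n))
    structure(list(dosage = dosage, map = map), class = "f2_genotypes")
  })
}

#' Simulate a pooled F3 seed lot
#'
#' Each surviving F3 family contributes exactly `seeds_per_family` seeds;
#' each seed's focal-locus genotype is drawn from its F2 parent's selfing
#' distribution (homozygote breeds true; heterozygote segregates 1/4, 1/2,
#' 1/4) and each seed is viable with its family's viability.
#'
#' @param f2_genotypes integer vector of F2 parental genotypes at the focal
#'   locus (0/1/2 dormant-allele count), one per family; an `f2_genotypes`
#'   object plus `focal_marker` is also accepted.
#' @param viability per-family viable fraction in \[0, 1\] (recycled).
#' @param seeds_per_family seeds contributed per family.
#' @param seed integer seed.
#' @param focal_marker marker id used when `f2_genotypes` is a table.
#' @return data.frame of class `seed_pool` with columns `family`, `genotype`
#'   (0/1/2), `viable`; `nrow = n_families * seeds_per_family`.
#' @export
simulate_f3_pool <- function(f2_genotypes, viability, seeds_per_family,
                             seed = 1, focal_marker = "SNP2") {
  if (inherits(f2_genotypes, "f2_genotypes")) {
    f2_genotypes <- f2_genotypes$dosage[, focal_marker]
  }
  g <- as.integer(f2_genotypes)
  n_fam <- length(g)
  if (n_fam == 0) stop("need at least one F3 family", call. = FALSE)
  stopifnot(all(g %in% 0:2))
  viability <- rep_len(viability, n_fam)
  if (any(viability < 0 | viability > 1)) {
    stop("viabilities must lie in [0, 1]", call. = FALSE)
  }
  spf <- check_count(seeds_per_family, "seeds_per_family")
  with_seed(seed, {
    fam <- rep(seq_len(n_fam), each = spf)
    parent <- g[fam]
    geno <- integer(length(fam))
    hom <- parent != 1L
    geno[hom] <- parent[hom]
    n_het <- sum(!hom)
    if (n_het > 0) {
      geno[!hom] <- sample(0:2, n_het, replace = TRUE,
                           prob = c(0.25, 0.5, 0.25))
    }
    viable <- runif(length(fam)) < viability[fam]
    structure(data.frame(family = fam, genotype = geno, viable = viable),
              class = c("seed_pool", "data.frame"))
  })
}

#' Design of the staged field-sampling experiment
#'
#' Germination and survival defaults emulate a dormant x non-dormant cross:
#' dormant homozygotes germinate late and bank heavily, non-dormant
#' homozygotes germinate early under unfavourable conditions and die more,
#' giving a closed-form relative viability of the non-dormant homozygote of
#' about 0.53 — inside the band observed in the field.
#'
#' @param n_f2_grown F2 plants grown per population.
#' @param n_families surviving F3 families.
#' @param seeds_per_family seeds pooled per family.
#' @param n_blocks,frames_per_block replication layout.
#' @param frame_area_cm2,soil_sampled_cm2 frame and soil-sample areas.
#' @param moved_prob probability a seed/seedling ends up outside its frame.
#' @param germination_model 3 x 3 matrix (rows DD, DN, NN; columns `germ1`,
#'   `germ2`, `bank`): probabilities of germinating by sampling point 1, by
#'   point 2, or entering the seed bank.  Row sums must be <= 1; the
#'   remainder dies ungerminated.
#' @param survival_model 3 x 2 matrix (columns `surv1`, `surv2`):
#'   per-genotype survival of germinants to their sampling point.
#' @param seed integer seed for [simulate_field_cohort()].
#' @return list of class `field_design`.
#' @export
field_design <- function(n_f2_grown = 248, n_families = 185,
                         seeds_per_family = 5, n_blocks = 2,
                         frames_per_block = 4, frame_area_cm2 = 600,
                         soil_sampled_cm2 = 18, moved_prob = 0.04,
                         germination_model = NULL, survival_model = NULL,
                         seed = 1) {
  if (is.null(germination_model)) {
    germination_model <- rbind(DD = c(0.15, 0.35, 0.40),
                               DN = c(0.30, 0.30, 0.25),
                               NN = c(0.55, 0.25, 0.05))
    colnames(germination_model) <- c("germ1", "germ2", "bank")
  }
  if (is.null(survival_model)) {
    survival_model <- rbind(DD = c(0.50, 0.70),
                            DN = c(0.45, 0.65),
                            NN = c(0.35, 0.55))
    colnames(survival_model) <- c("surv1", "surv2")
  }
  germination_model <- as.matrix(germination_model)
  survival_model <- as.matrix(survival_model)
  stopifnot(identical(rownames(germination_model), GENO_LEVELS),
            identical(rownames(survival_model), GENO_LEVELS))
  if (any(germination_model < 0) || any(survival_model < 0) ||
      any(germination_model > 1) || any(survival_model > 1)) {
    stop("germination/survival probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(rowSums(germination_model) > 1 + 1e-12)) {
    stop("per-genotype germ1 + germ2 + bank must be <= 1", call. = FALSE)
  }
  check_fraction(moved_prob, "moved_prob", 0, 1, hi_open = TRUE)
  if (soil_sampled_cm2 > frame_area_cm2 || soil_sampled_cm2 <= 0) {
    stop("soil_sampled_cm2 must be positive and <= frame_area_cm2",
         call. = FALSE)
  }
  structure(list(n_f2_grown = check_count(n_f2_grown, "n_f2_grown"),
                 n_families = check_count(n_families, "n_families"),
                 seeds_per_family = check_count(seeds_per_family,
                                                "seeds_per_family"),
                 n_blocks = check_count(n_blocks, "n_blocks"),
                 frames_per_block = check_count(frames_per_block,
                                                "frames_per_block"),
                 frame_area_cm2 = frame_area_cm2,
                 soil_sampled_cm2 = soil_sampled_cm2,
                 moved_prob = moved_prob,
                 germination_model = germination_model,
                 survival_model = survival_model, seed = seed),
            class = "field_design")
}

#' Simulate a field cohort with destructive seedling and soil sampling
#'
#' Each frame sows an independent fate realization of the given pool.  A
#' viable seed either germinates by sampling point 1, germinates by point 2,
#' enters the seed bank, or dies ungerminated, per its genotype's
#' germination model; germinants survive to their sampling point per the
#' survival model.  Sampled seedlings sit outside the frame with probability
#' `moved_prob`; seed-bank seeds still inside the frame are recovered in the
#' soil sample with probability `soil_sampled_cm2 / frame_area_cm2`.
#'
#' @param pool a `seed_pool` from [simulate_f3_pool()].
#' @param design a [field_design()].
#' @param population label used in the emitted count table.
#' @return object of class `field_cohort`: list with `counts` (tidy
#'   population/block/sampling_point/genotype/count/location table), `fates`
#'   (per block x genotype bookkeeping), and `truth` — the closed-form
#'   starting/ending frequencies, mean fitness and marginal/relative
#'   fitnesses implied by the generative probabilities.
#' @export
simulate_field_cohort <- function(pool, design, population = "popA") {
  stopifnot(inherits(pool, "seed_pool"), inherits(design, "field_design"))
  gm <- design$germination_model
  sm <- design$survival_model
  viable <- pool[pool$viable, , drop = FALSE]
  if (nrow(viable) == 0) stop("pool contains no viable seeds", call. = FALSE)
  n_g <- table(factor(GENO_LEVELS[3 - viable$genotype], levels = GENO_LEVELS))
  start <- as.numeric(n_g) / sum(n_g)
  names(start) <- GENO_LEVELS

  # closed-form truth from the generative probabilities
  w <- gm[, "germ1"] * sm[, "surv1"] + gm[, "germ2"] * sm[, "surv2"] +
    gm[, "bank"]
  w_bar <- sum(start * w)
  end <- start * w / w_bar
  truth <- list(start = start, end = end, mean_fitness = w_bar,
                marginal_fitness = w, relative_fitness = w / max(w))

  with_seed(design$seed, {
    soil_p <- design$soil_sampled_cm2 / design$frame_area_cm2
    cols <- c("viable", "germ1", "germ2", "bank", "died_ungerm",
              "gc1", "out1", "gc2", "out2", "gc3")
    rows <- list(); fates <- list()
    for (b in seq_len(design$n_blocks)) {
      agg <- matrix(0, length(GENO_LEVELS), length(cols),
                    dimnames = list(GENO_LEVELS, cols))
      for (f in seq_len(design$frames_per_block)) {
        for (g in GENO_LEVELS) {
          ng <- n_g[[g]]
          if (ng == 0) next
          p <- c(g1s = gm[g, "germ1"] * sm[g, "surv1"],
                 g1d = gm[g, "germ1"] * (1 - sm[g, "surv1"]),
                 g2s = gm[g, "germ2"] * sm[g, "surv2"],
                 g2d = gm[g, "germ2"] * (1 - sm[g, "surv2"]),
                 bank = gm[g, "bank"],
                 died = 1 - gm[g, "germ1"] - gm[g, "germ2"] - gm[g, "bank"])
          cnt <- drop(rmultinom(1, ng, p))
          out1 <- rbinom(1, cnt[["g1s"]], design$moved_prob)
          out2 <- rbinom(1, cnt[["g2s"]], design$moved_prob)
          bank_in <- rbinom(1, cnt[["bank"]], 1 - design$moved_prob)
          recovered <- rbinom(1, bank_in, soil_p)
          agg[g, ] <- agg[g, ] + c(
            ng, cnt[["g1s"]] + cnt[["g1d"]], cnt[["g2s"]] + cnt[["g2d"]],
            cnt[["bank"]], cnt[["died"]],
            cnt[["g1s"]], out1, cnt[["g2s"]], out2, recovered)
        }
      }
      fates[[b]] <- agg
      for (g in GENO_LEVELS) {
        rows[[length(rows) + 1]] <- data.frame(
          population = population, block = b,
          sampling_point = c(1, 1, 2, 2, 3),
          genotype = g,
          count = c(agg[g, "gc1"] - agg[g, "out1"], agg[g, "out1"],
                    agg[g, "gc2"] - agg[g, "out2"], agg[g, "out2"],
                    agg[g, "gc3"]),
          location = c("inside", "outside", "inside", "outside", "soil"))
      }
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- NULL
    structure(list(counts = counts, fates = fates, truth = truth,
                   design = design, population = population),
              class = "field_cohort")
  })
}
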