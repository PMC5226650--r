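# End-to-end pipeline driver: scan -> LD profile -> local MLMM (default and
# forced start) -> pseudo-SNP pairscan -> variance components -> field
# fitness estimation, with YAML-serializable configuration.

#' Build and validate a pipeline run configuration
#'
#' With no input paths the pipeline simulates its inputs from the synthetic
#' generator at the given seed.  The configuration round-trips losslessly
#' through [save_config()] / [load_config()].
#'
#' @param out_dir directory for the report bundle.
#' @param seed root seed for every stochastic stage.
#' @param n_lines,n_markers,n_region_markers,fst,n_subpops synthetic-panel
#'   parameters (see [population_config()]).
#' @param region candidate region string `"chrom:start-end"`.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param maf_min MAF filter for the pairwise scan.
#' @param max_forward forward (and backward) MLMM steps.
#' @param genotypes_path,phenotypes_path optional input files replacing the
#'   simulated panel (VCF/TSV + CSV).
#' @param counts_path,viability_path optional field-experiment inputs
#'   replacing the simulated cohort.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, n_lines = 161, n_markers = 1000,
                       n_region_markers = 50, fst = 0.1, n_subpops = 2,
                       region = "5:18560000-18610000", alpha = 0.05,
                       maf_min = 0.05, max_forward = 4,
                       genotypes_path = NULL, phenotypes_path = NULL,
                       counts_path = NULL, viability_path = NULL) {
  check_fraction(alpha, "alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  check_fraction(maf_min, "maf_min", 0, 0.5)
  check_count(max_forward, "max_forward")
  parse_region(region)  # validates
  for (p in c(genotypes_path, phenotypes_path, counts_path, viability_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file does not exist: ", p, call. = FALSE)
    }
  }
  if (!is.null(genotypes_path) && is.null(phenotypes_path)) {
    stop("phenotypes_path is required when genotypes_path is given",
         call. = FALSE)
  }
  if (!is.null(counts_path) && is.null(viability_path)) {
    stop("viability_path is required when counts_path is given",
         call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = seed, n_lines = n_lines,
                 n_markers = n_markers, n_region_markers = n_region_markers,
                 fst = fst, n_subpops = n_subpops, region = region,
                 alpha = alpha, maf_min = maf_min, max_forward = max_forward,
                 genotypes_path = genotypes_path,
                 phenotypes_path = phenotypes_path,
                 counts_path = counts_path,
                 viability_path = viability_path),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: genome-wide mixed-model scan, LD profile from the top
#' regional marker, local multi-locus scans (default start and forced
#' SNP2-style start when present), the pairwise pseudo-SNP scan, the
#' local/global variance decomposition, and the field fitness estimators on
#' a simulated (or provided) cohort.  Writes six artifact files plus a run
#' log into `cfg$out_dir`; rerunning with the same configuration reproduces
#' the artifacts byte for byte.
#'
#' @param cfg a [run_config()].
#' @return named list of artifact paths plus the in-memory results,
#'   invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(f) file.path(cfg$out_dir, f)

  inputs <- stage("data", {
    if (is.null(cfg$genotypes_path)) {
      pc <- population_config(n_lines = cfg$n_lines,
                              n_markers = cfg$n_markers,
                              n_subpops = cfg$n_subpops, fst = cfg$fst,
                              n_region_markers = cfg$n_region_markers,
                              region = cfg$region, seed = cfg$seed)
      G <- simulate_structured_genotypes(pc)
      spec <- locus_spec(region = cfg$region)
      G <- plant_heterogeneity_locus(G, spec, seed = child_seed(cfg$seed, 1))
      y <- simulate_phenotype(G, spec, seed = child_seed(cfg$seed, 2))
      list(G = G, y = y, spec = spec,
           proxy_r2 = attr(G, "realized_proxy_r2"))
    } else {
      if (is.null(cfg$phenotypes_path)) {
        stop("phenotypes_path is required with genotypes_path")
      }
      G <- read_genotypes(cfg$genotypes_path)
      ph <- read_phenotypes(cfg$phenotypes_path)
      y <- ph$gr21[match(rownames(G$dosage), ph$line_id)]
      names(y) <- rownames(G$dosage)
      if (anyNA(y)) stop("phenotype missing for some lines")
      list(G = G, y = y, spec = locus_spec(region = cfg$region),
           proxy_r2 = NA_real_)
    }
  })
  G <- inputs$G; y <- inputs$y

  scan_res <- stage("scan", {
    K <- estimate_kinship(G)
    fit <- fit_null_lmm(y, K)
    res <- scan_single_marker(y, G, fit)
    list(K = K, fit = fit, res = res,
         threshold = bonferroni_threshold(cfg$alpha, nrow(res)))
  })
  write_tsv(transform(scan_res$res,
                      beta = round(beta, 6), p = signif(p, 6),
                      neg_log10_p = round(neg_log10_p, 4),
                      maf = round(maf, 6)),
            art("assoc_scan.tsv"))

  ld_res <- stage("ld", {
    reg_idx <- markers_in_region(G, cfg$region)
    reg_scan <- scan_res$res[scan_res$res$id %in% G$map$id[reg_idx], ]
    top <- reg_scan$id[which.min(reg_scan$p)]
    ld_profile(G, top, window = 50000)
  })
  write_tsv(transform(ld_res, r2 = round(r2, 6)), art("ld_profile.tsv"))

  mlmm_res <- stage("mlmm", {
    reg_idx <- markers_in_region(G, cfg$region)
    default_path <- mlmm(y, G, scan_res$K, max_forward = cfg$max_forward,
                         markers = reg_idx)
    forced <- if ("SNP2" %in% G$map$id[reg_idx]) {
      mlmm(y, G, scan_res$K, start_marker = "SNP2",
           max_forward = cfg$max_forward, markers = reg_idx)
    }
    list(default = default_path, forced = forced)
  })
  tab <- rbind(cbind(start = "default", mlmm_res$default$steps),
               if (!is.null(mlmm_res$forced)) {
                 cbind(start = "SNP2", mlmm_res$forced$steps)
               })
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "step"
  tab[num] <- lapply(tab[num], function(x) round(x, 6))
  write_tsv(tab, art("mlmm_path.tsv"))

  pair_res <- stage("pairscan", {
    ps <- make_pseudo_snps(G, cfg$region, maf_min = cfg$maf_min)
    list(ps = ps, res = scan_pseudo_snps(y, ps, scan_res$fit))
  })
  write_tsv(transform(utils::head(pair_res$res, 500),
                      beta = round(beta, 6), p = signif(p, 6),
                      neg_log10_p = round(neg_log10_p, 4),
                      maf = round(maf, 6)),
            art("pairscan.tsv"))

  vc_res <- stage("varcomp", {
    reg_idx <- markers_in_region(G, cfg$region)
    K_local <- estimate_kinship(G$dosage[, reg_idx, drop = FALSE])
    K_global <- estimate_kinship(G$dosage[, -reg_idx, drop = FALSE])
    local_global_decomposition(y, K_local, K_global)
  })
  jsonlite::write_json(
    list(region = cfg$region, v_local = vc_res$v_local,
         v_global = vc_res$v_global, v_noise = vc_res$v_noise),
    art("varcomp.json"), auto_unbox = TRUE, digits = 6)

  field_res <- stage("field", {
    if (is.null(cfg$counts_path)) {
      design <- field_design(seed = child_seed(cfg$seed, 3))
      f2_geno <- with_seed(child_seed(cfg$seed, 4), {
        stats::rbinom(design$n_families, 2, 0.5)
      })
      viab <- with_seed(child_seed(cfg$seed, 5), {
        stats::rbeta(design$n_families, 8, 2)
      })
      pool <- simulate_f3_pool(f2_geno, viab, design$seeds_per_family,
                               seed = child_seed(cfg$seed, 6))
      cohort <- simulate_field_cohort(pool, design)
      counts <- cohort$counts
      start <- starting_frequencies(f2_geno, viab, design$seeds_per_family)
      w_bar <- cohort$truth$mean_fitness
      truth <- cohort$truth
    } else {
      counts <- read_cohort_counts(cfg$counts_path)
      viab_tab <- read_viability(cfg$viability_path)
      start <- starting_frequencies(viab_tab$f2_genotype, viab_tab$viability,
                                    viab_tab$seeds)
      w_bar <- 0.5  # unknown without a census; relative fitnesses unaffected
      truth <- NULL
    }
    blocks <- sort(unique(counts$block))
    per_block <- lapply(blocks, function(b) {
      ft <- estimate_field_fitness(counts, start, w_bar, block = b)
      list(block = b, moved = attr(ft, "moved"),
           start = as.list(stats::setNames(ft$start, ft$genotype)),
           end = as.list(stats::setNames(ft$end, ft$genotype)),
           marginal = as.list(stats::setNames(ft$marginal, ft$genotype)),
           relative = as.list(stats::setNames(ft$relative, ft$genotype)))
    })
    list(per_block = per_block, truth = truth)
  })
  jsonlite::write_json(field_res$per_block, art("fitness.json"),
                       auto_unbox = TRUE, digits = 6)

  log_lines <- c(
    sprintf("ghostmap %s", as.character(utils::packageVersion("ghostmap"))),
    sprintf("R %s.%s", R.version$major, R.version$minor),
    sprintf("seed: %s", cfg$seed),
    sprintf("region: %s", cfg$region),
    sprintf("markers scanned: %d", nrow(scan_res$res)),
    sprintf("bonferroni threshold: %g", scan_res$threshold),
    sprintf("realized proxy r2: %s",
            formatC(inputs$proxy_r2, digits = 4, format = "f")),
    sprintf("pseudo-snps tested: %d", pair_res$ps$counts[["pairs"]]))
  writeLines(log_lines, art("run_log.txt"))

  artifacts <- c(scan = art("assoc_scan.tsv"), ld = art("ld_profile.tsv"),
                 mlmm = art("mlmm_path.tsv"), pairscan = art("pairscan.tsv"),
                 varcomp = art("varcomp.json"), fitness = art("fitness.json"))
  invisible(list(artifacts = artifacts, scan = scan_res, ld = ld_res,
                 mlmm = mlmm_res, pairscan = pair_res$res, varcomp = vc_res,
                 field = field_res, proxy_r2 = inputs$proxy_r2))
}
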