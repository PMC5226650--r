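# Allelic-heterogeneity procedures: the pairwise pseudo-SNP (logical OR)
# scan, the multi-locus mixed model with a forced start marker and
# extended-BIC step selection, and haplogroup assignment from SNP2-SNP4.

#' Build pseudo-SNPs from all marker pairs in a region
#'
#' Markers inside `region` with MAF >= `maf_min` are combined pairwise by
#' elementwise logical OR of their minor-allele dosages
#' (0|0 = 0, 1|0 = 1, 0|1 = 1, 1|1 = 1).  Dosages are stored once; pair
#' dosages are materialized lazily by [pseudo_dosage()] or block-wise by
#' [scan_pseudo_snps()].
#'
#' @param G a [genotype_matrix()].
#' @param region region containing the candidate markers.
#' @param maf_min minor-allele-frequency filter (default 0.05).
#' @return object of class `pseudo_snps`: list with the passing `dosage`
#'   submatrix, marker `ids`, integer `pairs` matrix (one row per unordered
#'   pair), and `counts` (markers in region, markers passing, pairs).
#' @export
make_pseudo_snps <- function(G, region, maf_min = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  check_fraction(maf_min, "maf_min", 0, 0.5)
  idx <- markers_in_region(G, region)
  maf <- marker_maf(G$dosage[, idx, drop = FALSE])
  pass <- idx[maf >= maf_min]
  k <- length(pass)
  if (k < 2) {
    stop(sprintf("only %d marker(s) in the region pass MAF >= %g; need >= 2",
                 k, maf_min), call. = FALSE)
  }
  # all unordered pairs (i < j), lexicographic
  i <- rep.int(seq_len(k - 1L), times = (k - 1L):1L)
  j <- sequence((k - 1L):1L) + i
  structure(list(dosage = G$dosage[, pass, drop = FALSE],
                 ids = G$map$id[pass],
                 pairs = cbind(i = i, j = j),
                 counts = c(markers_in_region = length(idx),
                            markers_passing = k,
                            pairs = k * (k - 1L) / 2)),
            class = "pseudo_snps")
}

#' @export
print.pseudo_snps <- function(x, ...) {
  cat(sprintf("<pseudo_snps> %d markers in region, %d passing MAF filter, %d pairs\n",
              x$counts[["markers_in_region"]], x$counts[["markers_passing"]],
              x$counts[["pairs"]]))
  invisible(x)
}

#' OR-encoded dosage of one pseudo-SNP
#'
#' @param ps a [make_pseudo_snps()] object.
#' @param k pair index (row of `ps$pairs`).
#' @return 0/1 dosage vector of the logical OR of the pair.
#' @export
pseudo_dosage <- function(ps, k) {
  pr <- ps$pairs[k, ]
  as.integer(ps$dosage[, pr[[1]]] | ps$dosage[, pr[[2]]])
}

#' Mixed-model scan over all pseudo-SNPs
#'
#' Every pair is tested exactly like a single marker in
#' [scan_single_marker()]'s fast path (shared variance ratio from the null
#' fit).  Monomorphic pseudo-SNPs get p = 1.
#'
#' @param y phenotype vector.
#' @param ps a [make_pseudo_snps()] object.
#' @param K kinship matrix.
#' @param X optional covariates.
#' @param block_size pairs tested per block (memory/speed trade-off).
#' @return data.frame with `id_i`, `id_j`, `maf`, `beta`, `p`,
#'   `neg_log10_p`, sorted by ascending p, ties broken by (i, j).
#' @export
scan_pseudo_snps <- function(y, ps, K, X = NULL, block_size = 20000L) {
  stopifnot(inherits(ps, "pseudo_snps"))
  null_fit <- if (inherits(K, "lmm_fit")) K else fit_null_lmm(y, K, X)
  Ut <- t(null_fit$eigen$vectors)
  D <- ps$dosage
  n_pairs <- nrow(ps$pairs)
  beta <- p <- maf <- numeric(n_pairs)
  for (start in seq(1L, n_pairs, by = block_size)) {
    sel <- start:min(start + block_size - 1L, n_pairs)
    P <- (D[, ps$pairs[sel, 1], drop = FALSE] |
            D[, ps$pairs[sel, 2], drop = FALSE]) + 0
    maf[sel] <- marker_maf(P)
    mono <- maf[sel] == 0
    tests <- gls_marker_tests(null_fit, Ut %*% P)
    beta[sel] <- tests$beta
    p[sel] <- ifelse(mono, 1, tests$p)
    beta[sel][mono] <- NA_real_
  }
  out <- data.frame(id_i = ps$ids[ps$pairs[, 1]],
                    id_j = ps$ids[ps$pairs[, 2]],
                    maf = maf, beta = beta, p = p,
                    neg_log10_p = -log10(p), stringsAsFactors = FALSE)
  out[order(out$p, out$id_i, out$id_j), , drop = FALSE]
}

# ML-likelihood extended BIC for a step with k marker cofactors.
ext_bic <- function(loglik_ml, n, k, m_total) {
  -2 * loglik_ml + k * log(n) + 2 * lchoose(m_total, k)
}

# Variance partition {explained, genetic, error} for a cofactor set.
partition_variance <- function(y, G, cofactors, fit) {
  if (length(cofactors) == 0) {
    vexp <- 0
  } else {
    D <- G$dosage[, cofactors, drop = FALSE]
    Xf <- cbind(1, D)
    # GLS coefficients at the fitted delta
    w <- 1 / (fit$eigen$values + fit$delta)
    sw <- sqrt(w)
    Ut <- t(fit$eigen$vectors)
    cf <- stats::lm.fit((Ut %*% Xf) * sw, (Ut %*% y) * sw)$coefficients
    cf[is.na(cf)] <- 0
    vexp <- stats::var(drop(Xf %*% cf))
  }
  tot <- vexp + fit$sigma_g2 + fit$sigma_e2
  c(explained = vexp / tot, genetic = fit$sigma_g2 / tot,
    error = fit$sigma_e2 / tot)
}

#' Multi-locus mixed model with forced start marker and extBIC
#'
#' Stepwise forward inclusion of markers as fixed cofactors, re-estimating
#' the variance components by REML after every inclusion, followed by the
#' same number of backward elimination steps (least significant cofactor
#' removed first).  The extended BIC of each step is
#' `-2 * loglik_ML + k * log(n) + 2 * log C(m, k)` for k cofactors among m
#' candidate markers, and the optimal step minimizes it.  If `start_marker`
#' is given it is forced in at the first forward step; otherwise the most
#' significant marker is chosen.
#'
#' @param y phenotype vector.
#' @param G a [genotype_matrix()].
#' @param K kinship matrix.
#' @param start_marker optional marker id forced in at step 1.
#' @param max_forward number of forward (and backward) steps.
#' @param criterion model-selection criterion; only `"extBIC"`.
#' @param markers optional ids/indices restricting the candidate set (e.g.
#'   a region for a local scan).
#' @return object of class `mlmm_path`: `steps` data.frame (direction,
#'   cofactors, sigma_g2, sigma_e2, extBIC, explained/genetic/error),
#'   `optimal_step` (0-based step index minimizing extBIC), and
#'   `optimal_cofactors`.
#' @export
mlmm <- function(y, G, K, start_marker = NULL, max_forward = 4,
                 criterion = "extBIC", markers = NULL) {
  criterion <- match.arg(criterion, "extBIC")
  stopifnot(inherits(G, "genotype_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  max_forward <- check_count(max_forward, "max_forward")
  if (max_forward >= n / 2) {
    stop("max_forward must be below n/2 (overfitting guard)", call. = FALSE)
  }
  cand <- resolve_markers(G, markers)
  poly <- apply(G$dosage[, cand, drop = FALSE], 2,
                function(col) stats::var(col, na.rm = TRUE) > 0)
  cand <- cand[poly]
  m_total <- length(cand)
  ids <- G$map$id
  if (!is.null(start_marker)) {
    if (!start_marker %in% ids[cand]) {
      stop("start_marker is absent or monomorphic", call. = FALSE)
    }
  }
  ek <- kinship_eigen(K)
  Ut <- t(ek$vectors)

  fit_step <- function(cofactors) {
    X <- if (length(cofactors)) cbind(1, G$dosage[, cofactors, drop = FALSE])
    else NULL
    fit <- fit_null_lmm(y, ek, X)
    ml <- optimize_delta(ek$values, fit$ys, fit$Xs, fit$logdet_XtX, "ml")
    list(fit = fit, loglik_ml = ml$loglik)
  }

  record <- function(direction, cofactors, st) {
    k <- length(cofactors)
    part <- partition_variance(y, G, cofactors, st$fit)
    data.frame(step = NA_integer_, direction = direction,
               n_cofactors = k,
               cofactors = paste(ids[cofactors], collapse = "+"),
               sigma_g2 = st$fit$sigma_g2, sigma_e2 = st$fit$sigma_e2,
               extBIC = ext_bic(st$loglik_ml, n, k, m_total),
               explained = part[["explained"]],
               genetic = part[["genetic"]], error = part[["error"]],
               stringsAsFactors = FALSE)
  }

  cofactors <- integer(0)
  st <- fit_step(cofactors)
  steps <- list(record("null", cofactors, st))

  for (k in seq_len(max_forward)) {
    remaining <- setdiff(cand, cofactors)
    if (length(remaining) == 0) break
    if (k == 1 && !is.null(start_marker)) {
      pick <- cand[match(start_marker, ids[cand])]
    } else {
      D <- G$dosage[, remaining, drop = FALSE]
      tests <- gls_marker_tests(st$fit, Ut %*% D)
      # ties: smallest p, then position, then id
      ordp <- order(tests$p, G$map$pos[remaining], ids[remaining])
      pick <- remaining[ordp[1]]
    }
    cofactors <- c(cofactors, pick)
    st <- fit_step(cofactors)
    steps[[length(steps) + 1]] <- record("forward", cofactors, st)
  }

  n_back <- length(cofactors)
  for (k in seq_len(n_back)) {
    # drop-one significance of each cofactor in the current model
    pvals <- vapply(seq_along(cofactors), function(i) {
      rest <- cofactors[-i]
      X <- if (length(rest)) cbind(1, G$dosage[, rest, drop = FALSE])
      else NULL
      f <- fit_null_lmm(y, ek, X)
      gls_marker_tests(f, Ut %*% G$dosage[, cofactors[i], drop = FALSE])$p
    }, numeric(1))
    drop_i <- which.max(pvals)
    cofactors <- cofactors[-drop_i]
    st <- fit_step(cofactors)
    steps[[length(steps) + 1]] <- record("backward", cofactors, st)
  }

  steps <- do.call(rbind, steps)
  steps$step <- seq_len(nrow(steps)) - 1L
  optimal <- steps$step[which.min(steps$extBIC)]
  opt_cof <- steps$cofactors[steps$step == optimal]
  opt_cof <- if (nzchar(opt_cof)) strsplit(opt_cof, "+", fixed = TRUE)[[1]]
  else character(0)
  structure(list(steps = steps, optimal_step = optimal,
                 optimal_cofactors = opt_cof, m_total = m_total),
            class = "mlmm_path")
}

#' @export
print.mlmm_path <- function(x, ...) {
  cat(sprintf("<mlmm_path> %d steps, optimal step %d (cofactors: %s)\n",
              nrow(x$steps) - 1, x$optimal_step,
              if (length(x$optimal_cofactors)) {
                paste(x$optimal_cofactors, collapse = ", ")
              } else "none"))
  invisible(x)
}

#' Phenotypic variance explained by the cofactors of an MLMM step
#'
#' @param path an [mlmm()] path.
#' @param step 0-based step index (0 = null model).
#' @return fraction of phenotypic variance attributed to the step's marker
#'   cofactors.
#' @export
variance_explained <- function(path, step) {
  stopifnot(inherits(path, "mlmm_path"))
  row <- match(step, path$steps$step)
  if (is.na(row)) stop("no such step", call. = FALSE)
  path$steps$explained[row]
}

#' Assign dormancy haplogroups from SNP2-SNP4
#'
#' D2, D3, D4 carry the dormant (minor) allele at exactly one of SNP2, SNP3,
#' SNP4 respectively; ND carries none.  Lines with dormant alleles at two or
#' more of the three tag SNPs — or a missing genotype — are `ambiguous`.
#'
#' @param G a [genotype_matrix()] containing markers SNP2, SNP3, SNP4 (or a
#'   3-column 0/1 matrix in that order).
#' @return data.frame with `line_id` and `haplogroup`.
#' @export
assign_haplogroups <- function(G) {
  d <- if (inherits(G, "genotype_matrix")) {
    need <- c("SNP2", "SNP3", "SNP4")
    if (!all(need %in% colnames(G$dosage))) {
      stop("SNP2, SNP3 and SNP4 must be present", call. = FALSE)
    }
    G$dosage[, need, drop = FALSE]
  } else {
    m <- as.matrix(G)
    stopifnot(ncol(m) == 3)
    colnames(m) <- c("SNP2", "SNP3", "SNP4")
    m
  }
  n_dormant <- rowSums(d > 0)
  hap <- rep("ambiguous", nrow(d))
  complete <- !apply(d, 1, anyNA)
  hap[complete & n_dormant == 0] <- "ND"
  hap[complete & n_dormant == 1 & d[, "SNP2"] == 1] <- "D2"
  hap[complete & n_dormant == 1 & d[, "SNP3"] == 1] <- "D3"
  hap[complete & n_dormant == 1 & d[, "SNP4"] == 1] <- "D4"
  data.frame(line_id = rownames(d) %||% as.character(seq_len(nrow(d))),
             haplogroup = hap, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
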