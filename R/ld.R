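# Linkage-disequilibrium statistics used to expose long-range proxy
# structure around the dormancy locus.

#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of two dosage vectors.  On inbred 0/1 data
#' this equals the haploid D^2 / (p1 q1 p2 q2).  Missing values are handled
#' pairwise-complete with a minimum of 10 complete pairs.
#'
#' @param x,y dosage vectors of equal length (>= 3), both polymorphic.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (any(!ok) && sum(ok) < 10) {
    stop("fewer than 10 complete pairs after removing missing dosages",
         call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 lines", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("LD is undefined for monomorphic input", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' LD profile around a focal marker
#'
#' r-squared between the focal marker and every polymorphic marker within
#' `window` bp on the same chromosome, ordered by position.  Monomorphic
#' markers are kept with `r2 = NA` and flagged.
#'
#' @param G a [genotype_matrix()].
#' @param focal focal marker id.
#' @param window half-width of the window in bp.
#' @return data.frame with `id`, `pos`, `r2`, `monomorphic`.
#' @export
ld_profile <- function(G, focal, window) {
  stopifnot(inherits(G, "genotype_matrix"))
  fi <- match(focal, G$map$id)
  if (is.na(fi)) stop("focal marker not found: ", focal, call. = FALSE)
  xf <- G$dosage[, fi]
  if (stats::var(xf, na.rm = TRUE) == 0) {
    stop("focal marker is monomorphic", call. = FALSE)
  }
  sel <- which(G$map$chrom == G$map$chrom[fi] &
                 abs(G$map$pos - G$map$pos[fi]) <= window)
  sel <- sel[order(G$map$pos[sel])]
  mono <- vapply(sel, function(j) {
    stats::var(G$dosage[, j], na.rm = TRUE) == 0
  }, logical(1))
  r2 <- rep(NA_real_, length(sel))
  r2[!mono] <- vapply(sel[!mono], function(j) ld_r2(xf, G$dosage[, j]),
                      numeric(1))
  data.frame(id = G$map$id[sel], pos = G$map$pos[sel], r2 = r2,
             monomorphic = mono, row.names = NULL, stringsAsFactors = FALSE)
}
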