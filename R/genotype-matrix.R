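#' Genotype matrix for inbred lines
#'
#' A light container pairing a lines x markers dosage matrix with its marker
#' map.  Inbred accession panels carry haploid-like 0/1 minor-allele dosages;
#' F2 material uses 0/1/2 allele counts (see [simulate_f2()]).
#'
#' @param dosage numeric matrix, lines in rows, markers in columns.  Column
#'   names must match `map$id`; row names are line ids (generated if absent).
#' @param map data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   one row per marker, in the same order as the columns of `dosage`.
#' @param lines optional data.frame of per-line metadata (e.g. `line_id`,
#'   `subpop`, `latitude`).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, map, lines = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(map), all(c("id", "chrom", "pos") %in% names(map)),
            nrow(map) == ncol(dosage))
  map$id <- as.character(map$id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  rownames(map) <- NULL
  if (anyDuplicated(map$id)) stop("duplicated marker ids", call. = FALSE)
  colnames(dosage) <- map$id
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("line_%03d", seq_len(nrow(dosage)))
  }
  if (is.null(lines)) {
    lines <- data.frame(line_id = rownames(dosage),
                        stringsAsFactors = FALSE)
  }
  structure(list(dosage = dosage, map = map, lines = lines),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d markers on chromosome(s) %s\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$map$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Indices of markers falling inside a region
#'
#' @param G a [genotype_matrix()].
#' @param region region spec accepted by [parse_region()].
#' @return integer vector of column indices (1-based inclusive coordinates).
#' @export
markers_in_region <- function(G, region) {
  region <- parse_region(region)
  which(G$map$chrom == region$chrom &
          G$map$pos >= region$start & G$map$pos <= region$end)
}

#' Minor allele frequency per marker
#'
#' For inbred 0/1 dosages the allele frequency equals the dosage mean; the
#' MAF folds it onto \[0, 0.5\].  Missing dosages are ignored.
#'
#' @param G a [genotype_matrix()] or a dosage matrix.
#' @return numeric vector of per-marker MAF.
#' @export
marker_maf <- function(G) {
  d <- if (inherits(G, "genotype_matrix")) G$dosage else as.matrix(G)
  p <- colMeans(d, na.rm = TRUE)
  pmin(p, 1 - p)
}
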