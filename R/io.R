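# Readers and writers for the pipeline's plain-text formats: minimal VCF
# (via vcfR), TSV dosage matrices, CSV phenotype / cohort-count / viability
# tables, and YAML run configurations.

#' Read a genotype matrix from VCF or TSV
#'
#' VCF genotypes are parsed with vcfR; only biallelic records are kept
#' (multi-allelic sites are skipped with a warning).  For inbred accession
#' panels (`panel = "inbred"`) GT 0/0 maps to dosage 0, 1/1 to 1, and
#' heterozygous calls to missing; for F2 material (`panel = "f2"`) dosages
#' are 0/1/2 allele counts.  Positions are 1-based as in VCF.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param panel `"inbred"` or `"f2"`; controls heterozygote handling.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           panel = c("inbred", "f2")) {
  format <- match.arg(format)
  panel <- match.arg(panel)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    stopifnot(all(c("id", "chrom", "pos") %in% names(tab)))
    map <- tab[, c("id", "chrom", "pos")]
    d <- t(as.matrix(tab[, setdiff(names(tab), c("id", "chrom", "pos")),
                         drop = FALSE]))
    colnames(d) <- map$id
    return(genotype_matrix(d, map))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stop("no variants in ", path, call. = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipped %d multi-allelic site(s)", sum(multi)),
            call. = FALSE)
    v <- v[!multi, ]
    fix <- vcfR::getFIX(v)
  }
  if (nrow(fix) == 0) stop("no biallelic variants in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  alt_count <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  alt_count[gt %in% c("0/0", "0")] <- 0
  alt_count[gt %in% c("0/1", "1/0")] <- if (panel == "f2") 1 else NA
  alt_count[gt %in% c("1/1", "1")] <- if (panel == "f2") 2 else 1
  id <- fix[, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- sprintf("c%sp%s", fix[noid, "CHROM"], fix[noid, "POS"])
  map <- data.frame(id = id, chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]), stringsAsFactors = FALSE)
  genotype_matrix(t(alt_count), map)
}

#' Write a genotype matrix as minimal VCF or TSV
#'
#' @param G a [genotype_matrix()] (or `f2_genotypes`; 0/1/2 dosages emit
#'   0/0, 0/1, 1/1 calls).
#' @param path output file.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  d <- G$dosage
  map <- G$map
  if (format == "tsv") {
    tab <- cbind(map, as.data.frame(t(d), check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  f2 <- any(d == 2, na.rm = TRUE)
  code <- function(x) {
    out <- rep("./.", length(x))
    out[!is.na(x) & x == 0] <- "0/0"
    out[!is.na(x) & x == 1] <- if (f2) "0/1" else "1/1"
    out[!is.na(x) & x == 2] <- "1/1"
    out
  }
  body <- apply(d, 2, code)  # markers in columns
  lines <- c("##fileformat=VCFv4.2",
             "##source=ghostmap",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  recs <- vapply(seq_len(nrow(map)), function(j) {
    paste(c(map$chrom[j], format(map$pos[j], scientific = FALSE), map$id[j],
            "A", "T", ".", "PASS", ".", "GT", body[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, recs), path)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' CSV with columns `line_id`, `gr21` (0-100) and optionally `latitude`.
#'
#' @param path CSV file.
#' @return data.frame with those columns.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("line_id", "gr21") %in% names(tab)))
  tab
}

#' @rdname read_phenotypes
#' @param gr21 named GR21 vector (names = line ids).
#' @param latitude optional latitude vector aligned with `gr21`.
#' @export
write_phenotypes <- function(gr21, path, latitude = NULL) {
  tab <- data.frame(line_id = names(gr21), gr21 = round(as.numeric(gr21), 4))
  if (!is.null(latitude)) tab$latitude <- latitude
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write cohort count tables
#'
#' CSV with columns `population`, `block`, `sampling_point` (1, 2, 3),
#' `genotype` (DD, DN, NN), `count`, `location` (inside, outside, soil).
#'
#' @param path CSV file.
#' @return data.frame of counts.
#' @export
read_cohort_counts <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "block", "sampling_point", "genotype", "count",
            "location")
  stopifnot(all(need %in% names(tab)))
  tab
}

#' @rdname read_cohort_counts
#' @param counts tidy count table (e.g. `simulate_field_cohort()$counts`).
#' @export
write_cohort_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-family viability table
#'
#' CSV with columns `family_id`, `f2_genotype` (DD/DN/NN or 0/1/2),
#' `viability`, `seeds`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_viability <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family_id", "f2_genotype", "viability", "seeds")
                %in% names(tab)))
  tab
}
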