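# Internal helpers: seeded RNG scopes, argument checks, region parsing.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child stream from a root seed by a fixed offset; kept < 2^31 - 1.
child_seed <- function(seed, offset) {
  ((as.numeric(seed) %% 1e6) * 1009 + as.numeric(offset)) %% 2147483647
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (if (lo_open) x <= lo else x < lo) ||
      (if (hi_open) x >= hi else x > hi)) {
    stop(sprintf("`%s` must be a number in %s%g, %g%s, got %s",
                 name, if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]",
                 paste(format(x), collapse = ",")), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < min || x != floor(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Parse a genomic region
#'
#' Accepts either a `"chrom:start-end"` string or a list/vector with elements
#' `chrom`, `start`, `end`.  Coordinates are 1-based inclusive.
#'
#' @param region character scalar like `"5:18560000-18610000"`, or a list.
#' @return list with `chrom` (character), `start`, `end` (numeric).
#' @export
parse_region <- function(region) {
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) {
      stop("region must look like 'chrom:start-end'", call. = FALSE)
    }
    region <- list(chrom = m[2], start = as.numeric(m[3]),
                   end = as.numeric(m[4]))
  }
  region <- as.list(region)
  stopifnot(all(c("chrom", "start", "end") %in% names(region)))
  region$chrom <- as.character(region$chrom)
  region$start <- as.numeric(region$start)
  region$end <- as.numeric(region$end)
  if (region$end < region$start) stop("region end < start", call. = FALSE)
  region
}

offdiag <- function(m) m[lower.tri(m)]
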