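#' Fragment set
#'
#' Container for the fragments of one sequencing library on one contig.
#' Coordinates are 0-based half-open. `total_count` is the library-wide
#' number of retained fragments (across all contigs), which is the
#' denominator of the per-nucleotide negative-binomial test; it may exceed
#' the number of fragments held for the contig.
#'
#' @param contig Chromosome name.
#' @param start,end Integer vectors of fragment coordinates, 0-based
#'   half-open (`start < end`).
#' @param total_count Library-wide retained-fragment count; defaults to the
#'   number of fragments supplied.
#' @return An object of class `fragment_set`: a list with elements `contig`,
#'   `start`, `end`, `total_count`.
#' @export
fragment_set <- function(contig, start, end, total_count = length(start)) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end))
    stop("start and end must have equal length")
  if (any(start < 0L))
    stop("fragment start coordinates must be >= 0")
  if (any(start >= end))
    stop("fragments must have start < end")
  total_count <- as.integer(total_count)
  if (length(total_count) != 1L || is.na(total_count) || total_count < length(start))
    stop("total_count must be a single integer >= number of fragments held")
  ord <- order(start, end)
  structure(
    list(contig = as.character(contig), start = start[ord], end = end[ord],
         total_count = total_count),
    class = "fragment_set"
  )
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %s: %d fragments (library total %d)\n",
              x$contig, length(x$start), x$total_count))
  invisible(x)
}

#' @export
length.fragment_set <- function(x) length(x$start)

#' Per-base coverage track
#'
#' @param contig Chromosome name.
#' @param origin 0-based start coordinate of the covered interval.
#' @param values Non-negative integer coverage, one value per base.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(contig, origin, values) {
  values <- as.numeric(values)
  if (any(values < 0)) stop("coverage values must be non-negative")
  structure(
    list(contig = as.character(contig), origin = as.integer(origin),
         values = values),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s:[%d,%d) mean %.2f\n", x$contig, x$origin,
              x$origin + length(x$values), mean(x$values)))
  invisible(x)
}

#' Per-base p-value track
#'
#' Aligned 1:1 with the coverage tracks it was computed from.
#'
#' @param contig Chromosome name.
#' @param origin 0-based start coordinate.
#' @param pvalues Numeric vector of p-values in \[0, 1\], one per base.
#' @return An object of class `pvalue_track`.
#' @export
pvalue_track_new <- function(contig, origin, pvalues) {
  pvalues <- as.numeric(pvalues)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  structure(
    list(contig = as.character(contig), origin = as.integer(origin),
         pvalues = pvalues),
    class = "pvalue_track"
  )
}

#' @export
print.pvalue_track <- function(x, ...) {
  cat(sprintf("<pvalue_track> %s:[%d,%d) min %.3g\n", x$contig, x$origin,
              x$origin + length(x$pvalues),
              if (length(x$pvalues)) min(x$pvalues) else NA_real_))
  invisible(x)
}

# internal: check two tracks cover the same interval of the same contig
check_aligned <- function(a, b) {
  if (!identical(a$contig, b$contig) || a$origin != b$origin ||
      length(a$values %||% a$pvalues) != length(b$values %||% b$pvalues))
    stop("tracks are misaligned: contig, origin and length must agree")
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
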