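#' Load fragments from a coordinate-sorted BAM/SAM file
#'
#' Builds the fragment set of one contig from an alignment file, applying
#' the standard STARR-seq read filters: records below a MAPQ cutoff are
#' dropped, and (optionally) duplicate fragments — identical
#' (contig, start, end) — are collapsed to one. Properly paired reads
#' contribute their template span (one fragment per pair, taken from the
#' leftmost mate); unpaired or improperly paired reads contribute their read
#' span. `total_count` is computed library-wide over all contigs with the
#' same filters, because the negative-binomial test uses library totals.
#'
#' SAM input is converted (sorted and indexed) on the fly; BAM input must be
#' coordinate-sorted and indexed.
#'
#' @param alignment_file Path to a BAM (with `.bai` index) or SAM file.
#' @param contig Contig to extract fragments for; must exist in the header.
#' @param mapq_min Minimum mapping quality to retain a record (default 20).
#' @param dedup Drop duplicate fragments with identical coordinates
#'   (default `TRUE`; disable for libraries where duplicates are genuine,
#'   e.g. targeted designs with re-sampled inserts).
#' @return A [fragment_set()].
#' @export
load_fragments <- function(alignment_file, contig, mapq_min = 20L,
                           dedup = TRUE) {
  if (!file.exists(alignment_file))
    stop("alignment file not found: ", alignment_file)
  if (mapq_min < 0) stop("mapq_min must be >= 0")
  ext <- tolower(tools::file_ext(alignment_file))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(alignment_file, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  } else {
    bam <- alignment_file
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("BAM index (.bai) not found for ", bam,
           "; index the coordinate-sorted file first")
  }
  header <- Rsamtools::scanBamHeader(bam)[[1]]
  if (!contig %in% names(header$targets))
    stop("contig not present in alignment header: ", contig)

  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "mapq", "flag", "isize", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$mapq) & rec$mapq >= mapq_min & !is.na(rec$pos)
  rname <- as.character(rec$rname[keep])
  pos <- rec$pos[keep]
  flag <- rec$flag[keep]
  isize <- rec$isize[keep]
  qwidth <- rec$qwidth[keep]

  proper <- bitwAnd(flag, 2L) == 2L & !is.na(isize) & isize != 0L
  # pair span from the leftmost mate only; mate records are redundant
  left <- proper & isize > 0L
  single <- !proper
  f_contig <- c(rname[left], rname[single])
  f_start <- c(pos[left] - 1L, pos[single] - 1L)
  f_end <- c(pos[left] - 1L + isize[left], pos[single] - 1L + qwidth[single])

  ok <- f_start < f_end
  f_contig <- f_contig[ok]; f_start <- f_start[ok]; f_end <- f_end[ok]
  if (dedup) {
    dup <- duplicated(data.frame(f_contig, f_start, f_end))
    f_contig <- f_contig[!dup]; f_start <- f_start[!dup]; f_end <- f_end[!dup]
  }
  on_contig <- f_contig == contig
  fragment_set(contig, f_start[on_contig], f_end[on_contig],
               total_count = length(f_start))
}

#' Per-base coverage of a fragment set over an interval
#'
#' `values[i]` counts the fragments `f` with `f.start <= origin + i - 1 <
#' f.end` (0-based). Runs in time linear in the number of fragments plus the
#' interval length via difference-array accumulation.
#'
#' @param frags A [fragment_set()].
#' @param interval Length-2 numeric, 0-based half-open `(start, end)`.
#' @return A [coverage_track()] with `origin = interval[1]`.
#' @export
compute_coverage <- function(frags, interval) {
  stopifnot(inherits(frags, "fragment_set"))
  a <- as.integer(interval[1]); b <- as.integer(interval[2])
  if (a < 0 || a >= b) stop("interval must satisfy 0 <= start < end")
  len <- b - a
  s <- pmax(frags$start, a)
  e <- pmin(frags$end, b)
  keep <- s < e
  inc <- tabulate(s[keep] - a + 1L, nbins = len + 1L)
  dec <- tabulate(e[keep] - a + 1L, nbins = len + 1L)
  coverage_track(frags$contig, a, cumsum(inc - dec)[seq_len(len)])
}

#' Load a coverage track from a bedGraph file
#'
#' @param path 4-column bedGraph (0-based half-open intervals).
#' @param contig Contig to extract.
#' @param interval Length-2 numeric, 0-based half-open; bases not covered by
#'   any bedGraph line get value 0.
#' @return A [coverage_track()].
#' @export
load_bedgraph <- function(path, contig, interval) {
  a <- as.integer(interval[1]); b <- as.integer(interval[2])
  if (a < 0 || a >= b) stop("interval must satisfy 0 <= start < end")
  len <- b - a
  has_data <- file.exists(path) && {
    lns <- readLines(path, warn = FALSE)
    any(nzchar(trimws(lns)) & !startsWith(trimws(lns), "track") &
          !startsWith(trimws(lns), "#"))
  }
  if (!has_data) return(coverage_track(contig, a, numeric(len)))
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop("failed to parse bedGraph ", path, ": ",
                             conditionMessage(e))
  )
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == contig]
  if (length(gr) > 1 &&
      !IRanges::isDisjoint(GenomicRanges::ranges(gr)))
    stop("overlapping bedGraph intervals on ", contig,
         ": coverage is ambiguous")
  vals <- numeric(len)
  st <- GenomicRanges::start(gr) - 1L  # back to 0-based
  en <- GenomicRanges::end(gr)
  sc <- gr$score
  for (i in seq_along(sc)) {
    lo <- max(st[i], a); hi <- min(en[i], b)
    if (lo < hi) vals[(lo - a + 1L):(hi - a)] <- sc[i]
  }
  coverage_track(contig, a, vals)
}

#' Write a coverage or p-value track as bedGraph
#'
#' Runs of equal values are merged; zero-valued runs are omitted (a reload
#' with [load_bedgraph()] restores them as 0).
#'
#' @param track A [coverage_track()] or [pvalue_track_new()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  vals <- track$values %||% track$pvalues
  r <- rle(vals)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values != 0
  df <- data.frame(chrom = track$contig,
                   start = track$origin + starts[keep],
                   end = track$origin + ends[keep],
                   value = r$values[keep])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write silencer calls as BED6+
#'
#' Columns: contig, start, end, name, score, strand ("."), raw window
#' p-value, adjusted p-value, similarity score, strength ratio. The BED
#' score is `min(1000, round(-10 * log10(adjusted p)))`. Lines starting with
#' `#` carry provenance (e.g. the thresholds used).
#'
#' @param calls Data frame of calls as returned by [call_silencers()],
#'   sorted by (contig, start).
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("#", header), con)
  if (nrow(calls)) {
    ord <- order(calls$contig, calls$start)
    if (!identical(ord, seq_len(nrow(calls))))
      stop("calls must be sorted by (contig, start)")
    score <- pmin(1000, round(-10 * log10(calls$adjusted_p)))
    score[!is.finite(score)] <- 1000
    df <- data.frame(calls$contig, calls$start, calls$end, calls$name,
                     score, ".",
                     signif(calls$window_p, 6), signif(calls$adjusted_p, 6),
                     signif(calls$similarity_score, 6),
                     signif(calls$strength_ratio, 6))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read back a BED6+ call file written by [write_calls_bed()]
#'
#' @param path Path to the call file.
#' @return Data frame with columns contig, start, end, name, score, strand,
#'   window_p, adjusted_p, similarity_score, strength_ratio.
#' @export
read_calls_bed <- function(path) {
  lns <- readLines(path, warn = FALSE)
  lns <- lns[nzchar(lns) & !startsWith(lns, "#")]
  cols <- c("contig", "start", "end", "name", "score", "strand",
            "window_p", "adjusted_p", "similarity_score", "strength_ratio")
  if (!length(lns)) {
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                        cols))
    return(df)
  }
  df <- read.table(text = lns, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 6)
    stop("expected a BED6+ call file with at least 6 columns")
  names(df) <- cols[seq_len(min(ncol(df), length(cols)))]
  df
}

#' Read a two-column chrom.sizes table
#'
#' @param path Tab-separated file: contig name, length.
#' @return Named integer vector of contig lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("contig", "length"))
  stats::setNames(as.integer(df$length), df$contig)
}
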