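#' Pipeline configuration
#'
#' All thresholds of the silencer-calling pipeline in one object. Defaults
#' are the published operating point: per-base p-value threshold 1e-5
#' paired with a count-difference prescreen of 12, 601-bp windows, a 3/4
#' passing-base fraction, cosine similarity with threshold 0.9, BH
#' correction and a 1e-5 reporting threshold.
#'
#' @param p_thresh Per-base p-value threshold for anchors and for the
#'   window passing fraction.
#' @param min_diff Minimum `control - treat` count difference at an anchor.
#' @param window_size Candidate-window width in bp (odd; the anchor sits at
#'   the exact center).
#' @param frac Minimum fraction of window bases with `p < p_thresh`.
#' @param similarity_metric One of `"cosine"`, `"euclidean"`, `"pearson"`,
#'   `"gradient"`.
#' @param similarity_threshold Windows with a similarity score above this
#'   are discarded.
#' @param correction `"BH"` or `"bonferroni"`, applied across the surviving
#'   windows.
#' @param report_thresh Maximum corrected window p-value to report a call.
#' @param window_p_method Per-window aggregate of per-base p-values used
#'   for overlap resolution and correction: `"min"` (default) or
#'   `"median"`.
#' @param pseudocount Pseudocount used in the per-call strength ratio.
#' @return A list of class `fastnr_config`.
#' @export
fastnr_config <- function(p_thresh = 1e-5, min_diff = 12L,
                          window_size = 601L, frac = 0.75,
                          similarity_metric = "cosine",
                          similarity_threshold = 0.9,
                          correction = c("BH", "bonferroni"),
                          report_thresh = 1e-5,
                          window_p_method = c("min", "median"),
                          pseudocount = 1) {
  if (window_size %% 2L != 1L) stop("window_size must be odd")
  if (frac < 0 || frac > 1) stop("frac must lie in [0, 1]")
  similarity_metric <- match.arg(similarity_metric,
                                 c("cosine", "euclidean", "pearson",
                                   "gradient"))
  structure(
    list(p_thresh = p_thresh, min_diff = as.integer(min_diff),
         window_size = as.integer(window_size), frac = frac,
         similarity_metric = similarity_metric,
         similarity_threshold = similarity_threshold,
         correction = match.arg(correction),
         report_thresh = report_thresh,
         window_p_method = match.arg(window_p_method),
         pseudocount = pseudocount),
    class = "fastnr_config"
  )
}

#' Find anchor nucleotides
#'
#' An anchor is a single nucleotide that passes both the count-difference
#' prescreen and the per-base p-value threshold; anchors seed candidate
#' windows.
#'
#' @param ptrack A [pvalue_track_new()] object.
#' @param mask Logical prescreen vector from [prescreen_mask()], aligned
#'   with `ptrack`.
#' @param p_thresh Per-base p-value threshold (default 1e-5).
#' @param count_diff Optional integer vector of `control - treat`
#'   differences, aligned with `ptrack`, recorded per anchor.
#' @return Data frame with columns `contig`, `position` (0-based),
#'   `pvalue`, `count_diff`, in coordinate order.
#' @export
find_anchors <- function(ptrack, mask, p_thresh = 1e-5, count_diff = NULL) {
  if (length(mask) != length(ptrack$pvalues))
    stop("mask and p-value track are misaligned")
  hit <- which(mask & ptrack$pvalues < p_thresh)
  data.frame(
    contig = rep(ptrack$contig, length(hit)),
    position = ptrack$origin + hit - 1L,
    pvalue = ptrack$pvalues[hit],
    count_diff = if (is.null(count_diff)) rep(NA_integer_, length(hit))
                 else as.integer(count_diff[hit]),
    stringsAsFactors = FALSE
  )
}

#' Extend an anchor into a fixed-width window
#'
#' The window is centered on the anchor — `(window_size - 1) / 2` bases each
#' side — and clamped to the contig, which may shorten it near the edges.
#'
#' @param position Anchor coordinate(s), 0-based.
#' @param contig_length Contig length in bp.
#' @param window_size Window width (odd, default 601).
#' @return Data frame with 0-based half-open `start`, `end` columns.
#' @export
extend_window <- function(position, contig_length, window_size = 601L) {
  if (window_size %% 2L != 1L) stop("window_size must be odd")
  half <- (window_size - 1L) %/% 2L
  data.frame(start = pmax(0L, as.integer(position) - half),
             end = pmin(as.integer(contig_length),
                        as.integer(position) + half + 1L))
}

#' Passing-base fraction filter for one window
#'
#' A window is kept when at least `frac` of its (possibly clamped) bases
#' have a p-value below `p_thresh`.
#'
#' @param window Length-2 numeric, 0-based half-open `(start, end)`.
#' @param ptrack A [pvalue_track_new()] covering the window.
#' @param frac Minimum passing fraction (default 3/4, inclusive).
#' @param p_thresh Per-base p-value threshold (default 1e-5).
#' @return List with `keep` (logical) and `passing_fraction`.
#' @export
fraction_filter <- function(window, ptrack, frac = 0.75, p_thresh = 1e-5) {
  i <- window_slice(window, ptrack)
  pf <- mean(ptrack$pvalues[i] < p_thresh)
  list(keep = pf >= frac, passing_fraction = pf)
}

#' Aggregate p-value of one window
#'
#' @param window Length-2 numeric, 0-based half-open `(start, end)`.
#' @param ptrack A [pvalue_track_new()] covering the window.
#' @param method `"min"` (default) or `"median"`.
#' @return The aggregate p-value.
#' @export
window_pvalue <- function(window, ptrack, method = c("min", "median")) {
  method <- match.arg(method)
  i <- window_slice(window, ptrack)
  switch(method,
         min = min(ptrack$pvalues[i]),
         median = stats::median(ptrack$pvalues[i]))
}

# indices into a track for a 0-based half-open window; errors when empty or
# outside the track span
window_slice <- function(window, ptrack) {
  s <- as.integer(window[1]); e <- as.integer(window[2])
  if (s >= e) stop("empty window")
  lo <- s - ptrack$origin + 1L
  hi <- e - ptrack$origin
  if (lo < 1L || hi > length(ptrack$pvalues))
    stop("window outside the p-value track span")
  lo:hi
}

#' Resolve overlapping candidate windows
#'
#' Greedy selection in ascending window p-value order: a window is kept iff
#' it overlaps no already-kept window, so in any shared region the window
#' with the smaller p-value wins. Ties on p-value are broken by leftmost
#' start, then smallest end, which makes the result deterministic.
#'
#' @param windows Data frame with `start`, `end`, `window_p` columns (plus
#'   any others, carried through).
#' @return The kept rows, sorted by coordinate and pairwise disjoint.
#' @export
resolve_overlaps <- function(windows) {
  if (!nrow(windows)) return(windows)
  ord <- order(windows$window_p, windows$start, windows$end)
  w <- windows[ord, , drop = FALSE]
  kept_s <- integer(0); kept_e <- integer(0); keep <- logical(nrow(w))
  for (i in seq_len(nrow(w))) {
    if (!any(w$start[i] < kept_e & w$end[i] > kept_s)) {
      keep[i] <- TRUE
      kept_s <- c(kept_s, w$start[i]); kept_e <- c(kept_e, w$end[i])
    }
  }
  out <- w[keep, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call silencers from paired STARR-seq libraries
#'
#' The full pipeline: per-base coverage for both libraries; per-nucleotide
#' negative-binomial depletion p-values; count-difference prescreen;
#' anchors; centered fixed-width windows; passing-fraction filter; overlap
#' resolution (smaller window p-value wins); curve-similarity filter
#' (windows whose reporter and input curves are too similar are discarded);
#' multiple-testing correction across the surviving windows; and the final
#' corrected-p reporting threshold. Fully deterministic for fixed inputs
#' and configuration.
#'
#' @param treat [fragment_set()] of the reporter cDNA library.
#' @param control [fragment_set()] of the input insert DNA library.
#' @param config A [fastnr_config()].
#' @param contig_length Contig length in bp; defaults to the largest
#'   fragment end seen in either library.
#' @param verbose Emit one message per stage with the surviving count.
#' @return Data frame of calls: `contig`, `start`, `end`, `name`,
#'   `window_p`, `adjusted_p`, `similarity_score`, `similarity_index`,
#'   `strength_ratio`, `passing_fraction`, sorted and pairwise disjoint.
#' @export
call_silencers <- function(treat, control, config = fastnr_config(),
                           contig_length = NULL, verbose = FALSE) {
  stopifnot(inherits(treat, "fragment_set"),
            inherits(control, "fragment_set"))
  if (!identical(treat$contig, control$contig))
    stop("libraries are on different contigs")
  if (is.null(contig_length))
    contig_length <- max(treat$end, control$end)
  L <- as.integer(contig_length)
  say <- function(...) if (verbose) message(sprintf(...))

  tcov <- compute_coverage(treat, c(0L, L))
  ccov <- compute_coverage(control, c(0L, L))
  ptr <- pvalue_track(tcov, ccov, treat$total_count, control$total_count)
  mask <- prescreen_mask(tcov, ccov, config$min_diff)
  diff <- ccov$values - tcov$values
  anchors <- find_anchors(ptr, mask, config$p_thresh, count_diff = diff)
  say("anchors passing prescreen and p < %g: %d", config$p_thresh,
      nrow(anchors))
  if (!nrow(anchors)) return(empty_calls())

  win <- extend_window(anchors$position, L, config$window_size)
  # vectorized passing fraction via a cumulative count of passing bases
  cs <- c(0, cumsum(ptr$pvalues < config$p_thresh))
  pf <- (cs[win$end + 1L] - cs[win$start + 1L]) / (win$end - win$start)
  win <- win[pf >= config$frac, , drop = FALSE]
  pf <- pf[pf >= config$frac]
  win <- unique(cbind(win, passing_fraction = pf))
  say("windows passing the %.2f fraction filter: %d", config$frac,
      nrow(win))
  if (!nrow(win)) return(empty_calls())

  win$window_p <- vapply(seq_len(nrow(win)), function(i) {
    window_pvalue(c(win$start[i], win$end[i]), ptr, config$window_p_method)
  }, numeric(1))
  win <- resolve_overlaps(win)
  say("windows after overlap resolution: %d", nrow(win))

  sim <- vapply(seq_len(nrow(win)), function(i) {
    u <- tcov$values[(win$start[i] + 1L):win$end[i]]
    v <- ccov$values[(win$start[i] + 1L):win$end[i]]
    x <- win$start[i]:(win$end[i] - 1L)
    c(score = similarity_score(u, v, config$similarity_metric, x = x),
      cosd = cosine_distance(u, v))
  }, numeric(2))
  win$similarity_score <- sim["score", ]
  win$cosine_distance <- sim["cosd", ]
  win <- win[win$similarity_score <= config$similarity_threshold, ,
             drop = FALSE]
  say("windows passing the similarity filter (score <= %g): %d",
      config$similarity_threshold, nrow(win))
  if (!nrow(win)) return(empty_calls())

  win$adjusted_p <- if (config$correction == "BH") bh_adjust(win$window_p)
                    else bonferroni_adjust(win$window_p)
  win <- win[win$adjusted_p < config$report_thresh, , drop = FALSE]
  say("calls with corrected p < %g: %d", config$report_thresh, nrow(win))
  if (!nrow(win)) return(empty_calls())

  strength <- vapply(seq_len(nrow(win)), function(i) {
    ts <- sum(tcov$values[(win$start[i] + 1L):win$end[i]])
    cs2 <- sum(ccov$values[(win$start[i] + 1L):win$end[i]])
    -log2((ts + config$pseudocount) / (cs2 + config$pseudocount))
  }, numeric(1))

  data.frame(
    contig = treat$contig,
    start = win$start, end = win$end,
    name = sprintf("NRE_%d", seq_len(nrow(win))),
    window_p = win$window_p, adjusted_p = win$adjusted_p,
    similarity_score = win$similarity_score,
    similarity_index = similarity_index(pmax(win$cosine_distance, 0)),
    strength_ratio = strength,
    passing_fraction = win$passing_fraction,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

empty_calls <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             name = character(0), window_p = numeric(0),
             adjusted_p = numeric(0), similarity_score = numeric(0),
             similarity_index = numeric(0), strength_ratio = numeric(0),
             passing_fraction = numeric(0), stringsAsFactors = FALSE)
}
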