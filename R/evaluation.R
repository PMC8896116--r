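#' Detection power against a truth set
#'
#' A truth region counts as recovered when at least one call overlaps it by
#' at least 1 bp (each truth region counted once regardless of call
#' multiplicity). Power is recovered / total truth regions.
#'
#' @param calls Data frame with `start`, `end` columns (0-based half-open),
#'   e.g. from [call_silencers()].
#' @param truth Truth-region data frame (same coordinate convention).
#' @return List: `n_calls`, `n_truth`, `n_recovered`, `power`, and
#'   `n_calls_overlapping_truth` (calls touching any truth region).
#' @export
detection_power <- function(calls, truth) {
  if (!nrow(truth)) stop("truth set is empty")
  ir_t <- IRanges::IRanges(truth$start + 1L, truth$end)
  ir_c <- IRanges::IRanges(calls$start + 1L, calls$end)
  hit_t <- IRanges::countOverlaps(ir_t, ir_c) > 0
  hit_c <- IRanges::countOverlaps(ir_c, ir_t) > 0
  list(n_calls = nrow(calls), n_truth = nrow(truth),
       n_recovered = sum(hit_t), power = mean(hit_t),
       n_calls_overlapping_truth = sum(hit_c))
}

#' Venn counts between two call sets
#'
#' An element of `a` is "both" iff it overlaps at least one element of `b`
#' by >= 1 bp (and symmetrically); the reported `both` uses the
#' `a`-perspective count. Each input set must be internally disjoint.
#'
#' @param a,b Data frames with `start`, `end` columns (0-based half-open).
#' @return Named list `only_a`, `only_b`, `both`.
#' @export
callset_overlap <- function(a, b) {
  ir_a <- IRanges::IRanges(a$start + 1L, a$end)
  ir_b <- IRanges::IRanges(b$start + 1L, b$end)
  if (!IRanges::isDisjoint(ir_a)) stop("call set a is internally overlapping")
  if (!IRanges::isDisjoint(ir_b)) stop("call set b is internally overlapping")
  both_a <- sum(IRanges::countOverlaps(ir_a, ir_b) > 0)
  both_b <- sum(IRanges::countOverlaps(ir_b, ir_a) > 0)
  list(only_a = length(ir_a) - both_a, only_b = length(ir_b) - both_b,
       both = both_a)
}

#' Silencer strength ratio of a call
#'
#' `-log2((sum treat coverage + eps) / (sum control coverage + eps))` over
#' the call interval: larger values mean stronger depletion of reporter
#' cDNA, i.e. a stronger silencer. The pseudocount keeps
#' fully-depleted calls finite.
#'
#' @param call Length-2 numeric `(start, end)` (0-based half-open) or a
#'   one-row data frame with `start`, `end`.
#' @param treat,control [coverage_track()]s covering the call.
#' @param pseudocount Added to both sums (default 1).
#' @return The strength ratio.
#' @export
strength_ratio <- function(call, treat, control, pseudocount = 1) {
  if (is.data.frame(call)) call <- c(call$start[1], call$end[1])
  s <- as.integer(call[1]); e <- as.integer(call[2])
  i <- (s - treat$origin + 1L):(e - treat$origin)
  -log2((sum(treat$values[i]) + pseudocount) /
          (sum(control$values[i]) + pseudocount))
}

#' Correlation between silencer strength and curve similarity
#'
#' Pearson correlation between the similarity index (`-log2` cosine
#' distance) and the strength ratio across calls. Requires at least 3 calls
#' with finite values; otherwise (or under zero variance) the correlation
#' is undefined and `NA` is returned with a warning.
#'
#' @param calls Call data frame with `similarity_index` and
#'   `strength_ratio` columns, e.g. from [call_silencers()].
#' @return The correlation, or `NA` when undefined.
#' @export
similarity_strength_correlation <- function(calls) {
  ok <- is.finite(calls$similarity_index) & is.finite(calls$strength_ratio)
  if (sum(ok) < 3) {
    warning("fewer than 3 calls with finite similarity and strength; ",
            "correlation undefined")
    return(NA_real_)
  }
  x <- calls$similarity_index[ok]; y <- calls$strength_ratio[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Run the packaged spike-in benchmark end-to-end
#'
#' Simulates paired libraries ([simulate_benchmark()]), calls silencers at
#' each removal level with one shared configuration, and evaluates
#' detection power against the spiked truth regions.
#'
#' @param config A [sim_config()].
#' @param call_config A [fastnr_config()].
#' @param removal_fractions Removal levels; defaults to the config's.
#' @return List with `calls` (per-level call tables), `truth` (per-level
#'   truth tables), `control` (base library), and `report` — a data frame
#'   with one row per removal level: `removal_fraction`, `n_calls`,
#'   `n_recovered`, `power`, `n_calls_overlapping_truth`.
#' @export
run_benchmark <- function(config = sim_config(),
                          call_config = fastnr_config(),
                          removal_fractions = config$removal_fractions) {
  sim <- simulate_benchmark(config, removal_fractions)
  L <- config$contig_length
  calls <- list(); rows <- list()
  for (key in names(sim$treat)) {
    cl <- call_silencers(sim$treat[[key]], sim$control,
                         config = call_config, contig_length = L)
    ev <- detection_power(cl, sim$truth[[key]])
    calls[[key]] <- cl
    rows[[key]] <- data.frame(
      removal_fraction = as.numeric(key), n_calls = ev$n_calls,
      n_recovered = ev$n_recovered, power = ev$power,
      n_calls_overlapping_truth = ev$n_calls_overlapping_truth)
  }
  list(calls = calls, truth = sim$truth, control = sim$control,
       report = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
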