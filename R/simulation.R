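#' Spike-in simulation configuration
#'
#' Parameters of the synthetic STARR-seq benchmark: a contig is tiled into
#' `bin_size` windows; per-bin fragment counts are drawn from a negative
#' binomial (genome-wide sequencing depth is overdispersed relative to
#' Poisson); bins covered by at least `min_reads` fragments are eligible,
#' and `n_regions` of them become spiked silencers by removing a fixed
#' fraction of their fragments from the reporter library.
#'
#' Defaults follow the published benchmark protocol: 400-bp bins, >= 100
#' fragments per eligible bin, 1,000 spiked regions, removal levels 30, 50,
#' 70 and 90%. The synthetic contig (8 Mb, mean 200 fragments per bin,
#' negative-binomial dispersion 10, fragment lengths uniform on 200-600 bp)
#' stands in for a real insert library so tests need no download.
#'
#' @param contig Synthetic contig name.
#' @param contig_length Contig length in bp.
#' @param n_regions Number of spiked silencer regions.
#' @param bin_size Bin width in bp.
#' @param min_reads Minimum fragments overlapping a bin for eligibility.
#' @param removal_fractions Default removal levels of the benchmark.
#' @param mean_frags_per_bin Mean of the per-bin fragment-count
#'   distribution.
#' @param dispersion Negative-binomial `size` of the per-bin counts.
#' @param frag_len_range Fragment lengths drawn uniformly from this range.
#' @param seed Integer seed; every stochastic step of the simulator derives
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(contig = "chrS", contig_length = 8e6,
                       n_regions = 1000L, bin_size = 400L,
                       min_reads = 100L,
                       removal_fractions = c(0.3, 0.5, 0.7, 0.9),
                       mean_frags_per_bin = 200, dispersion = 10,
                       frag_len_range = c(200L, 600L), seed = 1L) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (any(removal_fractions <= 0 | removal_fractions >= 1))
    stop("removal fractions must lie in (0, 1)")
  if (contig_length < bin_size)
    stop("contig_length must hold at least one complete bin")
  if (mean_frags_per_bin <= 0)
    stop("mean fragment count per bin must be positive")
  structure(
    list(contig = contig, contig_length = as.integer(contig_length),
         n_regions = as.integer(n_regions), bin_size = as.integer(bin_size),
         min_reads = as.integer(min_reads),
         removal_fractions = removal_fractions,
         mean_frags_per_bin = mean_frags_per_bin, dispersion = dispersion,
         frag_len_range = as.integer(frag_len_range),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a synthetic base (input insert) library
#'
#' Draws a per-bin fragment count from `NegBin(mu = mean_frags_per_bin,
#' size = dispersion)`, places each fragment's start uniformly within its
#' bin, and draws its length uniformly from `frag_len_range` (ends are
#' clipped at the contig end). Reproducible under the config seed.
#'
#' @param config A [sim_config()].
#' @return A [fragment_set()].
#' @export
generate_base_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nbins <- config$contig_length %/% config$bin_size
  withr::with_seed(config$seed, {
    counts <- rnbinom(nbins, mu = config$mean_frags_per_bin,
                      size = config$dispersion)
    n <- sum(counts)
    bin_of <- rep(seq_len(nbins) - 1L, counts)
    starts <- bin_of * config$bin_size +
      sample.int(config$bin_size, n, replace = TRUE) - 1L
    lens <- sample(seq(config$frag_len_range[1], config$frag_len_range[2]),
                   n, replace = TRUE)
    ends <- pmin(starts + lens, config$contig_length)
    fragment_set(config$contig, starts, ends)
  })
}

#' Select truth regions for spiking
#'
#' Tiles the contig into non-overlapping bins from coordinate 0, keeps the
#' bins overlapped by at least `min_reads` fragments, and samples
#' `n_regions` of them uniformly without replacement under the config seed.
#'
#' @param base The base [fragment_set()].
#' @param config A [sim_config()].
#' @return Data frame of disjoint truth regions: `contig`, `start`, `end`,
#'   `fragments_before` (overlap count at selection time), sorted by
#'   coordinate.
#' @export
select_truth_regions <- function(base, config) {
  stopifnot(inherits(base, "fragment_set"), inherits(config, "sim_config"))
  if (!length(base$start)) stop("base library is empty")
  nbins <- config$contig_length %/% config$bin_size
  if (nbins < 1L) stop("contig holds no complete bin")
  # fragments overlapping each bin (any overlap), via a difference array
  # over bin indices
  fb <- pmin(base$start %/% config$bin_size, nbins - 1L)
  lb <- pmin((base$end - 1L) %/% config$bin_size, nbins - 1L)
  inc <- tabulate(fb + 1L, nbins = nbins + 1L)
  dec <- tabulate(lb + 2L, nbins = nbins + 1L)
  overlap_count <- cumsum(inc - dec)[seq_len(nbins)]
  eligible <- which(overlap_count >= config$min_reads)
  if (length(eligible) < config$n_regions)
    stop(sprintf(
      "eligible bin pool (%d) smaller than requested regions (%d)",
      length(eligible), config$n_regions))
  chosen <- withr::with_seed(config$seed,
                             sample(eligible, config$n_regions))
  chosen <- sort(chosen)
  data.frame(
    contig = config$contig,
    start = (chosen - 1L) * config$bin_size,
    end = chosen * config$bin_size,
    fragments_before = overlap_count[chosen],
    stringsAsFactors = FALSE
  )
}

#' Spike silencers by removing reads from truth regions
#'
#' For each truth region, enumerates the fragments assigned to it and
#' removes `round(removal_fraction * k)` of them by uniform sampling
#' without replacement; fragments outside all truth regions are untouched.
#' A fragment overlapping more than one truth region is assigned to the
#' region containing its midpoint (falling back to the larger overlap, then
#' the leftmost region), so it can be removed at most once. The returned
#' library is the simulated reporter cDNA library.
#'
#' @param base The base [fragment_set()] (simulated input insert library).
#' @param truth Truth-region data frame from [select_truth_regions()].
#' @param removal_fraction Fraction of each region's fragments to remove,
#'   in (0, 1); 0 is permitted for degenerate no-effect checks.
#' @param seed Integer seed for the removal sampling.
#' @return List with `library` (the spiked [fragment_set()]) and `truth`
#'   (the input truth table with `removal_fraction`, `fragments_before`
#'   recomputed as the assigned count, and `fragments_removed` columns).
#' @export
spike_silencers <- function(base, truth, removal_fraction, seed = 1L) {
  stopifnot(inherits(base, "fragment_set"))
  if (removal_fraction < 0 || removal_fraction >= 1)
    stop("removal_fraction must lie in [0, 1)")
  if (nrow(truth) > 1) {
    o <- order(truth$start)
    if (any(truth$end[o][-nrow(truth)] > truth$start[o][-1]))
      stop("truth regions must be pairwise disjoint")
  }
  region <- assign_to_region(base$start, base$end, truth)
  n <- nrow(truth)
  assigned_counts <- tabulate(region, nbins = n)
  n_remove <- round(removal_fraction * assigned_counts)
  drop <- integer(0)
  if (sum(n_remove) > 0) {
    drop <- withr::with_seed(seed, {
      unlist(lapply(seq_len(n), function(r) {
        idx <- which(region == r)
        if (n_remove[r] > 0) sample(idx, n_remove[r]) else integer(0)
      }))
    })
  }
  keep <- setdiff(seq_along(base$start), drop)
  truth$removal_fraction <- removal_fraction
  truth$fragments_before <- assigned_counts
  truth$fragments_removed <- as.integer(n_remove)
  list(
    library = fragment_set(base$contig, base$start[keep], base$end[keep]),
    truth = truth
  )
}

# map each fragment to the index of the truth region it belongs to (NA when
# it overlaps none); midpoint rule on multiple overlaps, then larger
# overlap, then leftmost
assign_to_region <- function(start, end, truth) {
  n <- length(start)
  region <- rep(NA_integer_, n)
  if (!nrow(truth)) return(region)
  ts <- truth$start; te <- truth$end
  ord <- order(ts)
  ts <- ts[ord]; te <- te[ord]; orig <- seq_len(nrow(truth))[ord]
  # candidate regions via sorted search: regions with ts < end & te > start
  first <- findInterval(start, te) + 1L  # first region with te > start
  mid <- (start + end) %/% 2L
  cand <- which(first <= length(ts) & ts[pmin(first, length(ts))] < end)
  for (i in cand) {
    j <- first[i]
    hits <- integer(0)
    while (j <= length(ts) && ts[j] < end[i]) {
      hits <- c(hits, j); j <- j + 1L
    }
    if (!length(hits)) next
    if (length(hits) == 1L) { region[i] <- orig[hits]; next }
    inmid <- hits[ts[hits] <= mid[i] & mid[i] < te[hits]]
    if (length(inmid)) { region[i] <- orig[inmid[1L]]; next }
    ov <- pmin(end[i], te[hits]) - pmax(start[i], ts[hits])
    region[i] <- orig[hits[which.max(ov)]]
  }
  region
}

#' Run the full spike-in benchmark generator
#'
#' Generates the base library, selects a shared truth set, and spikes one
#' reporter library per removal level. The base library doubles as the
#' input insert (control) library, so outside the truth regions treat and
#' control coverage are identical base-for-base.
#'
#' @param config A [sim_config()].
#' @param removal_fractions Removal levels; defaults to the config's.
#' @return List with `control` (the base [fragment_set()]), `truth` (list
#'   of per-level truth tables, named by level), and `treat` (list of
#'   spiked [fragment_set()]s, named by level).
#' @export
simulate_benchmark <- function(config,
                               removal_fractions =
                                 config$removal_fractions) {
  base <- generate_base_library(config)
  truth0 <- select_truth_regions(base, config)
  treat <- list(); truth <- list()
  for (rf in removal_fractions) {
    sp <- spike_silencers(base, truth0, rf, seed = config$seed)
    key <- format(rf)
    treat[[key]] <- sp$library
    truth[[key]] <- sp$truth
  }
  list(control = base, truth = truth, treat = treat)
}

#' Write truth regions as BED6
#'
#' The removal fraction is recorded in the score column as a percentage
#' (e.g. 90 for removal 0.9).
#'
#' @param truth Truth table from [spike_silencers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  df <- data.frame(truth$contig, truth$start, truth$end,
                   sprintf("truth_%d", seq_len(nrow(truth))),
                   round(100 * (truth$removal_fraction %||% 0)), ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
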