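#' Negative-binomial CDF for the per-nucleotide depletion test
#'
#' Returns `P(X <= m)` for `X ~ NegBin(n, p)` counting the number of
#' failures before the n-th success with per-trial success probability `p`,
#' i.e. the sum over `i = 0..m` of `choose(i + n - 1, n - 1) p^n (1 - p)^i`.
#' Evaluated through the regularized incomplete beta identity
#' `I_p(n, m + 1)`, which stays numerically stable for `n` up to library
#' size (~1e9), where literal term summation is infeasible.
#'
#' @param m Observed failure count(s), integer `>= 0`.
#' @param n Target success count(s), integer `>= 1`.
#' @param p Per-trial success probability in `(0, 1]`.
#' @return `P(X <= m)`, vectorized over the inputs.
#' @export
nb_cdf <- function(m, n, p) {
  if (any(m < 0) || any(m != floor(m))) stop("m must be a non-negative integer")
  if (any(n < 1)) stop("n must be >= 1")
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  pbeta(p, n, m + 1)
}

#' Depletion p-value at one nucleotide
#'
#' Tests whether the reporter cDNA count at a nucleotide is lower than
#' expected given the input insert DNA count, using
#' `nb_cdf(treat_count, treat_total - treat_count,
#' (control_total - control_count) / control_total)`. Small values indicate
#' depletion of reporter cDNA, i.e. silencer activity.
#'
#' @param treat_count Reporter cDNA coverage at the nucleotide.
#' @param control_count Input insert DNA coverage at the nucleotide.
#' @param treat_total,control_total Library-wide fragment totals.
#' @return The depletion p-value, vectorized over counts.
#' @export
site_pvalue <- function(treat_count, control_count, treat_total,
                        control_total) {
  if (treat_total <= 0 || control_total <= 0)
    stop("library totals must be positive")
  if (any(treat_count > treat_total))
    stop("treat_count cannot exceed treat_total")
  if (any(control_count > control_total))
    stop("control_count cannot exceed control_total")
  if (any(control_count == control_total))
    stop("undefined site: control coverage equals the control library ",
         "total (success probability 0)")
  if (any(treat_count == treat_total))
    stop("undefined site: treat coverage equals the treat library total")
  nb_cdf(treat_count, treat_total - treat_count,
         (control_total - control_count) / control_total)
}

#' Per-nucleotide depletion p-values over an interval
#'
#' Element-wise [site_pvalue()] over aligned coverage tracks. Degenerate
#' sites where the test is undefined (coverage equal to the full library
#' total) are assigned p-value 1 so they can never be called.
#'
#' @param treat,control Aligned [coverage_track()]s (same contig, origin,
#'   length).
#' @param treat_total,control_total Library-wide fragment totals.
#' @return A [pvalue_track_new()] aligned with the inputs.
#' @export
pvalue_track <- function(treat, control, treat_total, control_total) {
  check_aligned(treat, control)
  tc <- treat$values; cc <- control$values
  pv <- rep(1, length(tc))
  ok <- tc < treat_total & cc < control_total
  if (any(ok))
    pv[ok] <- site_pvalue(tc[ok], cc[ok], treat_total, control_total)
  pvalue_track_new(treat$contig, treat$origin, pv)
}

#' Count-difference prescreen
#'
#' The cheap first screen of the pipeline: a nucleotide is a candidate only
#' if input insert coverage exceeds reporter cDNA coverage by at least
#' `min_diff` (default 12, paired with the 1e-5 per-base p-value threshold).
#'
#' @param treat,control Aligned [coverage_track()]s.
#' @param min_diff Minimum `control - treat` difference (default 12).
#' @return Logical vector, one element per base.
#' @export
prescreen_mask <- function(treat, control, min_diff = 12L) {
  check_aligned(treat, control)
  (control$values - treat$values) >= min_diff
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, returned in the original input order, each value
#' `>=` its raw p-value and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Bonferroni adjustment
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return `min(1, p * N)` element-wise.
#' @export
bonferroni_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "bonferroni")
}
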