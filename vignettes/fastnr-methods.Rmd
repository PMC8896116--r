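---
title: "Calling silencers from STARR-seq with fastnr: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling silencers from STARR-seq with fastnr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastnr)
```

## The problem

STARR-seq clones candidate DNA fragments downstream of a minimal promoter
so that each fragment transcribes itself; the abundance of a fragment in
the reporter cDNA library, relative to its abundance in the input insert
(plasmid) library, measures its regulatory activity. Enhancer callers look
for *enrichment* of reporter reads. Silencers — negative regulatory
elements (NREs) — do the opposite: they suppress their own transcription,
so they appear as *depletion* of reporter cDNA where the input insert
coverage is intact. fastnr detects that depletion at single-nucleotide
resolution and then uses the *shape* of the two coverage curves as an
orthogonal filter.

## The per-nucleotide count model

At a nucleotide, let `treatCount` be the reporter cDNA coverage,
`controlCount` the input insert coverage, and `treatTotal`,
`controlTotal` the library-wide fragment totals. The depletion p-value is
the negative-binomial CDF

\[
P(X \le m) \;=\; \sum_{i=0}^{m} \binom{i+n-1}{n-1} p^n (1-p)^i,
\qquad
\begin{aligned}
m &= \text{treatCount},\\
n &= \text{treatTotal} - \text{treatCount},\\
p &= \frac{\text{controlTotal} - \text{controlCount}}{\text{controlTotal}},
\end{aligned}
\]

i.e. the probability of seeing at most `m` failures before the `n`-th
success when each trial succeeds with probability `p`. Intuitively, each of
the `treatTotal` sequenced reporter fragments either covers this nucleotide
(a "failure") or not (a "success"); if the reporter library mirrored the
input, the chance of not covering the base would match the control
proportion. A small CDF value means the reporter coverage is lower than the
control coverage can explain.

Because `n` is on the order of the library size (up to ~1e9), the sum is
evaluated through the regularized incomplete beta identity
\(P(X \le m) = I_p(n, m+1)\) (`nb_cdf()`), not by literal summation; the
test suite checks the identity against exact term-by-term summation for all
`m, n <= 50` and against the reference CDF implementation at large `n`.
Two degenerate parameterizations cannot support a depletion claim and are
assigned p-value 1: `controlCount = controlTotal` (success probability 0)
and `treatCount = treatTotal`.

## The calling pipeline

`call_silencers()` runs, in order:

1. **Coverage** — per-base fragment coverage of both libraries
   (difference-array accumulation, linear time).
2. **Prescreen** — only bases with `controlCount - treatCount >= 12` are
   considered (`min_diff`; the default 12 is calibrated to the 1e-5
   per-base p-value threshold and avoids computing statistics where no
   call is possible).
3. **Anchors** — bases passing the prescreen with p < 1e-5 (`p_thresh`).
4. **Windows** — each anchor is extended to a 601-bp window, anchor at the
   exact center (300 bp each side); windows are clamped at contig edges
   and the clamped length is used downstream.
5. **Fraction filter** — keep windows in which at least 3/4 of the bases
   (inclusive comparison) have p < 1e-5.
6. **Overlap resolution** — windows get an aggregate p-value
   (`window_p_method`, default the minimum per-base p) and are selected
   greedily in ascending order; a window is kept iff it overlaps no
   already-kept window, so the smaller p-value wins any shared region.
   Ties break by leftmost start, then smallest end — the result is
   deterministic and pairwise disjoint.
7. **Similarity filter** — windows whose reporter and input coverage
   curves are too similar in shape are discarded (below).
8. **Correction** — BH (default) or Bonferroni across the surviving
   windows' aggregate p-values; calls need corrected p < 1e-5
   (`report_thresh`).

The caller consumes no randomness: repeated runs on identical inputs give
byte-identical BED output.

### Design choices that were genuinely open

* **Window aggregate p-value.** Overlap resolution needs a per-window
  p-value, and so does the correction step, but only per-base p-values are
  defined by the count model. We use the window minimum by default (it is
  order-consistent with anchor strength) and expose `"median"` as an
  alternative.
* **Pipeline order.** The similarity filter runs before correction, so the
  BH pool is the set of shape-filtered candidate windows; one p-value per
  window enters the correction.
* **Adjacent anchors.** Every anchor seeds its own window; deduplication
  happens only at overlap resolution. Merging anchor runs first would give
  essentially the same calls but make the window placement rule more
  complicated.
* **Fraction comparison at equality.** `>=` — a window with exactly 3/4
  passing bases is kept.

## Curve similarity

Over a candidate window, the reporter curve `u` and input curve `v` (raw
per-base counts, not library-normalized — the count scale is part of the
signal) are compared with one of four metrics: cosine distance, Euclidean
distance, Pearson correlation, or the gradient method (Pearson correlation
of the per-base slopes, invariant to vertical offsets). A true silencer
suppresses the reporter curve where the input curve is intact, so its two
curves should *disagree*; windows whose similarity score exceeds the
threshold (default 0.9) are discarded.

The single 0.9 threshold needs every metric on one "higher = more similar"
scale. We use: cosine `1 - distance`; Euclidean `1 / (1 + distance)` (the
metric is unbounded); Pearson and gradient as-is. The scale for each
metric, and the threshold itself, are configurable
(`similarity_metric`, `similarity_threshold`), because only the cosine
default is pinned down by how the similarity index
(`-log2` cosine distance) is defined. Two numerical policies matter:

* an all-zero reporter curve makes the cosine undefined; it is reported as
  maximal distance 1, because total depletion is the strongest silencer
  signal and must not be discarded on a technicality;
* a zero-variance curve makes the correlations undefined; they are
  reported as 0 ("no similarity evidence"), which keeps the window.

## The spike-in simulator

The simulator emulates the read-removal benchmark protocol: a contig is
tiled into 400-bp bins, bins covered by at least 100 fragments are
eligible, a fixed number of eligible bins become "true" silencers, and the
reporter library is the input library with a fixed fraction (30/50/70/90%)
of each truth bin's fragments removed uniformly at random. Removed counts
are `round(fraction * k)` (round-half-even); a fragment overlapping two
truth bins is assigned to the bin containing its midpoint so it can be
removed at most once.

The synthetic base library draws per-bin fragment counts from a negative
binomial (genome-wide sequencing depth is overdispersed; mean 200 per bin,
dispersion 10 — roughly a 30% coefficient of variation, typical of input
libraries), places fragment starts uniformly within bins, and draws
fragment lengths uniformly on 200–600 bp, a realistic STARR-seq insert
range. All stochastic steps derive from one integer seed.

**What the simulation does and does not show.** Because the reporter
library is a literal subset of the input library, the two coverage tracks
share their noise outside the removal: curve similarity is therefore
*higher* in this benchmark than between two independently sequenced
libraries. At moderate removal (30–70%) the surviving window is typically
discarded by the similarity filter at the default threshold, so measured
power is near zero there and then jumps at 90% removal, where deep
thinning makes the reporter curve both noisier and dip-shaped. Real
libraries are sequenced independently, so passing these tests demonstrates
correctness of the machinery and the direction of the power trend — power
non-decreasing in removal fraction — not the absolute power a real
experiment would achieve at each level. The tests also do not model PCR
duplicates, GC or shear bias, or mappability; bias correction is
deliberately out of scope.

## Problem sizes and benchmark configuration

The packaged benchmark used by the tests and by `scripts/acceptance.R` is
a 1,000-bin (400 kb) contig with ~200 fragments per bin and 50 spiked
regions — large enough that each stage (prescreen, windowing, overlap
resolution, similarity, correction) operates in its intended regime, small
enough to run in seconds. `sim_config()` defaults describe a larger 8-Mb
contig with 1,000 spiked regions for users who want the full-scale
protocol proportions; the simulator also accepts a real insert library
loaded with `load_fragments()` as the base in place of
`generate_base_library()`.

A worked run:

```{r benchmark}
cfg <- sim_config(contig_length = 400L * 1000L, n_regions = 50L, seed = 7L)
bm <- run_benchmark(cfg, removal_fractions = c(0.3, 0.9))
bm$report
suppressWarnings(similarity_strength_correlation(bm$calls[["0.9"]]))
```

The negative correlation between the similarity index and the strength
ratio (−log2 reporter/input reads) reproduces the qualitative finding that
stronger silencers have less similar curves.

## Known limitations

* One contig per call; multi-chromosome inputs are processed contig by
  contig (the CLI does this per `--contig`).
* No replicate handling or dispersion estimation: the negative-binomial
  test uses library totals only, as specified by the count model.
* The similarity threshold semantics for the unbounded Euclidean metric
  (via `1/(1+d)`) compress large distances; cosine is the recommended and
  default metric.
* The final call-count monotonicity under threshold tightening is a
  property of the data regimes we test (well-separated depleted regions),
  not a theorem: in pathological overlap configurations, removing a
  low-p window can admit two previously shadowed neighbours.
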