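test_that("find_anchors is the conjunction of prescreen and p threshold", {
  pv <- rep(1e-6, 10)
  pt <- pvalue_track_new("chr1", 100L, pv)
  mask <- rep(FALSE, 10); mask[c(6, 7)] <- TRUE
  a <- find_anchors(pt, mask)
  expect_equal(a$position, c(105L, 106L))
  expect_equal(a$pvalue, rep(1e-6, 2))

  expect_equal(nrow(find_anchors(pt, rep(FALSE, 10))), 0L)
  expect_error(find_anchors(pt, rep(TRUE, 5)), "misaligned")
})

test_that("find_anchors equals a brute-force position filter", {
  withr::with_seed(13, {
    pv <- stats::runif(500)^6
    mask <- stats::runif(500) < 0.3
    pt <- pvalue_track_new("chr1", 0L, pv)
    a <- find_anchors(pt, mask, p_thresh = 0.01)
    brute <- which(vapply(seq_along(pv),
                          function(i) mask[i] && pv[i] < 0.01, logical(1)))
    expect_equal(a$position, brute - 1L)
  })
})

test_that("extend_window centers on the anchor and clamps at edges", {
  w <- extend_window(10000L, contig_length = 1e6)
  expect_equal(c(w$start, w$end), c(9700L, 10301L))
  expect_equal(w$end - w$start, 601L)

  w <- extend_window(100L, contig_length = 1e6)
  expect_equal(c(w$start, w$end), c(0L, 401L))

  w <- extend_window(999999L, contig_length = 1e6)
  expect_equal(w$end, 1000000L)
  expect_error(extend_window(5L, 100L, window_size = 600L), "odd")
})

test_that("fraction_filter applies the inclusive 3/4 rule to actual length", {
  pv <- rep(1, 601); pv[1:451] <- 1e-6
  pt <- pvalue_track_new("chr1", 0L, pv)
  r <- fraction_filter(c(0, 601), pt)
  expect_true(r$keep)
  expect_equal(r$passing_fraction, 451 / 601)

  pv[451] <- 1  # 450 passing bases: 0.7488 < 0.75
  pt <- pvalue_track_new("chr1", 0L, pv)
  expect_false(fraction_filter(c(0, 601), pt)$keep)

  pt1 <- pvalue_track_new("chr1", 0L, rep(1e-7, 50))
  r <- fraction_filter(c(0, 50), pt1)
  expect_true(r$keep)
  expect_equal(r$passing_fraction, 1)
  expect_error(fraction_filter(c(10, 10), pt1), "empty")
})

test_that("window_pvalue aggregates per-base p-values deterministically", {
  pt <- pvalue_track_new("chr1", 0L, rep(1e-6, 20))
  expect_equal(window_pvalue(c(0, 20), pt, "min"), 1e-6)
  expect_equal(window_pvalue(c(0, 20), pt, "median"), 1e-6)

  pv <- rep(1e-5, 20); pv[7] <- 1e-8
  pt <- pvalue_track_new("chr1", 0L, pv)
  expect_equal(window_pvalue(c(0, 20), pt, "min"), 1e-8)
  expect_error(window_pvalue(c(0, 20), pt, "max"))

  withr::with_seed(4, {
    pv <- stats::runif(300)
    pt <- pvalue_track_new("chr1", 0L, pv)
    expect_equal(window_pvalue(c(50, 200), pt, "min"), min(pv[51:200]))
  })
})

test_that("resolve_overlaps keeps the smaller-p window in shared regions", {
  w <- data.frame(start = c(0L, 300L), end = c(601L, 901L),
                  window_p = c(1e-8, 1e-7))
  r <- resolve_overlaps(w)
  expect_equal(r$start, 0L)

  disj <- data.frame(start = c(0L, 1000L), end = c(601L, 1601L),
                     window_p = c(1e-8, 1e-7))
  expect_equal(nrow(resolve_overlaps(disj)), 2L)

  # chain A-B-C: A overlaps B, B overlaps C, A and C disjoint
  chain <- data.frame(start = c(0L, 500L, 1000L),
                      end = c(601L, 1101L, 1601L),
                      window_p = c(1e-6, 1e-9, 1e-7))
  expect_equal(resolve_overlaps(chain)$start, 500L)   # B smallest: B only
  chain$window_p <- c(1e-9, 1e-6, 1e-7)
  expect_equal(resolve_overlaps(chain)$start, c(0L, 1000L))  # B largest
  # ties broken by leftmost start: deterministic
  tie <- data.frame(start = c(100L, 0L), end = c(701L, 601L),
                    window_p = c(1e-8, 1e-8))
  expect_equal(resolve_overlaps(tie)$start, 0L)
})

test_that("call_silencers recovers a single planted depletion region", {
  ctrl <- make_dense_library()
  trt <- thin_region(ctrl, 3600L, 4000L, 0.9)
  calls <- call_silencers(trt, ctrl, contig_length = 8000L)
  expect_equal(nrow(calls), 1L)
  expect_true(calls$start < 4000L && calls$end > 3600L)
  expect_true(calls$adjusted_p < 1e-5)
  # depletion direction: window-average treat strictly below control
  tcov <- compute_coverage(trt, c(0, 8000))
  ccov <- compute_coverage(ctrl, c(0, 8000))
  i <- (calls$start + 1):calls$end
  expect_lt(mean(tcov$values[i]), mean(ccov$values[i]))
  expect_gt(calls$strength_ratio, 0)
})

test_that("identical libraries yield zero calls", {
  ctrl <- make_dense_library(len = 4000L)
  expect_equal(nrow(call_silencers(ctrl, ctrl, contig_length = 4000L)), 0L)
})

test_that("calls from nearby planted regions are disjoint and anchored", {
  ctrl <- make_dense_library(len = 12000L)
  trt <- thin_region(ctrl, 4000L, 4400L, 0.9, seed = 5L)
  trt <- thin_region(trt, 4600L, 5000L, 0.9, seed = 6L)
  calls <- call_silencers(trt, ctrl, contig_length = 12000L)
  expect_gt(nrow(calls), 0L)
  if (nrow(calls) > 1) {
    o <- order(calls$start)
    expect_true(all(calls$end[o][-nrow(calls)] <= calls$start[o][-1]))
  }
  # every call contains at least one anchor-grade base
  tcov <- compute_coverage(trt, c(0, 12000))
  ccov <- compute_coverage(ctrl, c(0, 12000))
  pt <- pvalue_track(tcov, ccov, trt$total_count, ctrl$total_count)
  msk <- prescreen_mask(tcov, ccov)
  for (i in seq_len(nrow(calls))) {
    j <- (calls$start[i] + 1):calls$end[i]
    expect_true(any(msk[j] & pt$pvalues[j] < 1e-5))
  }
})

test_that("the caller is deterministic for fixed inputs", {
  ctrl <- make_dense_library()
  trt <- thin_region(ctrl, 3600L, 4000L, 0.9)
  a <- call_silencers(trt, ctrl, contig_length = 8000L)
  b <- call_silencers(trt, ctrl, contig_length = 8000L)
  expect_identical(a, b)
})
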