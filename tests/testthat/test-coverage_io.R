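test_that("load_fragments applies the MAPQ filter to read pairs", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, data.frame(
    rname = "chr1", start = c(100L, 500L, 900L), end = c(300L, 700L, 1100L),
    mapq = c(30L, 19L, 25L)))
  fs <- load_fragments(sam, "chr1", mapq_min = 20)
  expect_equal(length(fs), 2L)
  expect_equal(fs$start, c(100L, 900L))
  expect_equal(fs$end, c(300L, 1100L))
  expect_equal(fs$total_count, 2L)
})

test_that("load_fragments returns an empty set for a contig with no reads", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, data.frame(rname = "chr1", start = 100L, end = 300L,
                                 mapq = 30L))
  fs <- load_fragments(sam, "chr2")
  expect_equal(length(fs), 0L)
  expect_equal(fs$total_count, 1L)  # totals stay library-wide
})

test_that("duplicate fragments are collapsed only when dedup is on", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, data.frame(rname = "chr1", start = c(100L, 100L),
                                 end = c(300L, 300L), mapq = 30L))
  expect_equal(length(load_fragments(sam, "chr1", dedup = TRUE)), 1L)
  expect_equal(length(load_fragments(sam, "chr1", dedup = FALSE)), 2L)
})

test_that("load_fragments is idempotent and validates its inputs", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, data.frame(rname = "chr1", start = c(100L, 900L),
                                 end = c(300L, 1100L), mapq = 30L))
  a <- load_fragments(sam, "chr1")
  b <- load_fragments(sam, "chr1")
  expect_identical(a, b)
  expect_error(load_fragments(sam, "chrZ"), "contig")
  bam <- Rsamtools::asBam(sam, destination = tempfile(), overwrite = TRUE)
  file.remove(paste0(bam, ".bai"))
  expect_error(load_fragments(bam, "chr1"), "index")
})

test_that("compute_coverage counts fragments per base", {
  fs <- fragment_set("chr1", c(0L, 5L), c(10L, 15L))
  cv <- compute_coverage(fs, c(0, 15))
  expect_equal(cv$values[8], 2)   # position 7 (0-based)
  expect_equal(cv$values[3], 1)   # position 2
  expect_equal(cv$values[13], 1)  # position 12
  empty <- fragment_set("chr1", integer(0), integer(0))
  expect_equal(compute_coverage(empty, c(0, 10))$values, numeric(10))
})

test_that("compute_coverage matches the brute-force membership oracle", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      L <- 2000L
      s <- sample.int(L - 1L, 1000L, replace = TRUE) - 1L
      e <- pmin(s + sample.int(300L, 1000L, replace = TRUE), L)
      fs <- fragment_set("chr1", s, e)
      cv <- compute_coverage(fs, c(0, L))
      oracle <- vapply(seq_len(L) - 1L,
                       function(pos) sum(fs$start <= pos & pos < fs$end),
                       numeric(1))
      expect_equal(cv$values, oracle)
      # conservation: total coverage equals total fragment length
      expect_equal(sum(cv$values), sum(fs$end - fs$start))
    }
  })
})

test_that("bedGraph round-trips and rejects malformed input", {
  bg <- tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t5\t3", bg)
  expect_equal(load_bedgraph(bg, "chr1", c(0, 8))$values,
               c(3, 3, 3, 3, 3, 0, 0, 0))

  writeLines(character(0), bg)
  expect_equal(load_bedgraph(bg, "chr1", c(0, 4))$values, numeric(4))

  tr <- coverage_track("chr1", 0L, c(0, 2, 2, 5, 0, 0, 1))
  out <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, out)
  expect_equal(load_bedgraph(out, "chr1", c(0, 7))$values, tr$values)

  writeLines(c("chr1\t0\t5\t3", "chr1\t3\t8\t2"), bg)
  expect_error(load_bedgraph(bg, "chr1", c(0, 10)), "overlap")
  writeLines("chr1\tnotanumber\t5\t3", bg)
  expect_error(load_bedgraph(bg, "chr1", c(0, 10)))
})

test_that("write_calls_bed emits BED6+ with the -10log10 score", {
  calls <- data.frame(contig = "chr22", start = 1000L, end = 1601L,
                      name = "NRE_1", window_p = 1e-7, adjusted_p = 1e-6,
                      similarity_score = 0.5, similarity_index = 1,
                      strength_ratio = 2, passing_fraction = 0.8)
  path <- tempfile(fileext = ".bed")
  write_calls_bed(calls, path)
  line <- readLines(path)[1]
  expect_match(line, "^chr22\t1000\t1601\t")
  expect_equal(as.integer(strsplit(line, "\t")[[1]][5]), 60L)

  back <- read_calls_bed(path)
  expect_equal(back$start, calls$start)
  expect_equal(back$end, calls$end)
  expect_equal(back$adjusted_p, calls$adjusted_p)

  write_calls_bed(calls[0, ], path)
  expect_equal(nrow(read_calls_bed(path)), 0L)

  two <- rbind(calls, transform(calls, start = 100L, end = 701L))
  expect_error(write_calls_bed(two, path), "sorted")
})

test_that("chrom.sizes tables load as named lengths", {
  p <- tempfile()
  writeLines(c("chr1\t248956422", "chr22\t50818468"), p)
  sz <- read_chrom_sizes(p)
  expect_equal(sz[["chr22"]], 50818468L)
})
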