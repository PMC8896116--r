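# Fixtures are built in code at test time; nothing binary ships with the
# package.

# Write a minimal coordinate-sorted SAM file. `pairs` is a data frame with
# columns rname, start (0-based fragment start), end (0-based half-open
# fragment end) and mapq; each row becomes one properly-paired read pair
# whose template span equals [start, end). Reads are 40 bp.
write_test_sam <- function(path, pairs,
                           contigs = c(chr1 = 10000L, chr2 = 5000L)) {
  rlen <- 40L
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  seq <- strrep("A", rlen)
  qual <- strrep("I", rlen)
  recs <- character(0)
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$start[i]; e <- pairs$end[i]
    tlen <- e - s
    p1 <- s + 1L                 # 1-based leftmost read position
    p2 <- e - rlen + 1L          # 1-based rightmost read position
    qn <- sprintf("frag%03d", i)
    recs <- c(recs,
      sprintf("%s\t99\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
              qn, pairs$rname[i], p1, pairs$mapq[i], rlen, p2, tlen,
              seq, qual),
      sprintf("%s\t147\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
              qn, pairs$rname[i], p2, pairs$mapq[i], rlen, p1, -tlen,
              seq, qual))
  }
  # coordinate order within the contig
  pos <- as.integer(sub("^[^\t]+\t[0-9]+\t[^\t]+\t([0-9]+)\t.*", "\\1", recs))
  rn <- sub("^[^\t]+\t[0-9]+\t([^\t]+)\t.*", "\\1", recs)
  recs <- recs[order(match(rn, names(contigs)), pos)]
  writeLines(c(hdr, recs), path)
  path
}

# Dense paired fragment sets for small end-to-end pipeline fixtures:
# `n_per_bin` fragments start in every `bin` bp bin of a `len` bp contig.
make_dense_library <- function(len = 8000L, bin = 400L, n_per_bin = 200L,
                               frag_len = c(200L, 600L), seed = 42L) {
  withr::with_seed(seed, {
    nbins <- len %/% bin
    starts <- rep((seq_len(nbins) - 1L) * bin, each = n_per_bin) +
      sample.int(bin, nbins * n_per_bin, replace = TRUE) - 1L
    lens <- sample(seq(frag_len[1], frag_len[2]), length(starts),
                   replace = TRUE)
    fragment_set("chrT", starts, pmin(starts + lens, len))
  })
}

# Remove `fraction` of the fragments overlapping [start, end) from a
# fragment set (deterministic under seed); used to plant one known
# depletion region without the full simulator.
thin_region <- function(frags, start, end, fraction, seed = 5L) {
  ov <- which(frags$start < end & frags$end > start)
  drop <- withr::with_seed(seed, sample(ov, round(fraction * length(ov))))
  keep <- setdiff(seq_along(frags$start), drop)
  fragment_set(frags$contig, frags$start[keep], frags$end[keep])
}

# Exact PMF summation of the negative-binomial CDF (independent oracle for
# nb_cdf): sum_{i=0}^{m} choose(i+n-1, n-1) p^n (1-p)^i, evaluated in log
# space term by term.
nb_cdf_oracle <- function(m, n, p) {
  i <- 0:m
  sum(exp(lchoose(i + n - 1, n - 1) + n * log(p) + i * log1p(-p)))
}
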