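test_that("merge_peaks combines overlapping and adjacent intervals", {
  x <- data.frame(chrom = "chr1", start = c(0L, 10L), end = c(10L, 20L))
  m <- merge_peaks(x)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 20L)

  x <- data.frame(chrom = "chr1", start = c(0L, 5L), end = c(10L, 15L))
  expect_equal(merge_peaks(x)$end, 15L)

  x <- data.frame(chrom = "chr1", start = c(0L, 20L), end = c(10L, 30L))
  expect_equal(nrow(merge_peaks(x)), 2L)

  # idempotence, coverage, and sortedness on random interval sets
  set.seed(42)
  for (i in 1:10) {
    x <- data.frame(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                    start = sample.int(500L, 30))
    x$end <- x$start + sample.int(50L, 30)
    m <- merge_peaks(x)
    expect_identical(m, merge_peaks(m))
    expect_true(all(diff(m$start[m$chrom == "chr1"]) > 0))
    # every input bp covered
    for (j in seq_len(nrow(x))) {
      hit <- m$chrom == x$chrom[j] & m$start <= x$start[j] & m$end >= x$end[j]
      expect_true(any(hit))
    }
    # no two intervals touch
    for (chrom in unique(m$chrom)) {
      d <- m[m$chrom == chrom, ]
      if (nrow(d) > 1L) expect_true(all(d$start[-1L] > d$end[-nrow(d)]))
    }
  }
})

test_that("merge_peaks rejects malformed intervals", {
  bad <- data.frame(chrom = "chr1", start = 10L, end = 10L, name = "badrec")
  expect_error(merge_peaks(bad), "badrec")
})

test_that("center_and_resize uses the floored center and drops overflow", {
  lens <- c(chr1 = 5000L)
  r <- center_and_resize(data.frame(chrom = "chr1", start = 1000L, end = 1100L),
                         300L, lens)
  expect_equal(c(r$start, r$end), c(900L, 1200L))
  # odd length: center 1050.5 floors to 1050
  r <- center_and_resize(data.frame(chrom = "chr1", start = 1000L, end = 1101L),
                         300L, lens)
  expect_equal(c(r$start, r$end), c(900L, 1200L))
  # near the chromosome start: dropped and reported
  expect_message(
    r <- center_and_resize(data.frame(chrom = "chr1", start = 50L, end = 150L),
                           300L, lens),
    "dropped")
  expect_equal(nrow(r), 0L)
  expect_equal(nrow(attr(r, "dropped")), 1L)
  # fixed point for even widths
  x <- data.frame(chrom = "chr1", start = 2000L, end = 2300L)
  r1 <- center_and_resize(x, 300L, lens)
  expect_equal(r1$start, x$start)
  expect_equal(r1$end, x$end)
})

test_that("filter_records drops non-ACGT sequences and excluded chromosomes", {
  rec <- data.frame(
    chrom = c("chr8", "chr1_KI270706v1_random", "chr2"),
    seq = c("ACGTACGT", "ACGTACGT", "ACGNACGT"),
    stringsAsFactors = FALSE)
  out <- filter_records(rec)
  expect_equal(out$chrom, "chr8")
  expect_equal(attr(out, "drop_counts")[["excluded_chrom"]], 1L)
  expect_equal(attr(out, "drop_counts")[["non-ACGT"]], 1L)
  # lowercase (soft-masked) bases are legitimate sequence
  soft <- data.frame(chrom = "chr3", seq = "acgtACGT", stringsAsFactors = FALSE)
  expect_equal(nrow(filter_records(soft)), 1L)
})

test_that("peak_overlap statistic matches the union formula", {
  # 10 vs 10 peaks, 5 qualifying one-to-one overlaps
  a <- data.frame(chrom = "chr1", start = seq(0L, 900L, 100L))
  a$end <- a$start + 50L
  b <- a
  b$start[6:10] <- b$start[6:10] + 2000L # move 5 away entirely
  b$end <- b$start + 50L
  ov <- peak_overlap(a, b)
  expect_equal(ov$n_pairs, 5L)
  expect_equal(ov$statistic, 5 / 15)
  expect_identical(peak_overlap(a, b)$statistic, peak_overlap(b, a)$statistic)
  # identical and disjoint sets
  expect_equal(peak_overlap(a, a)$statistic, 1.0)
  d <- a; d$start <- d$start + 10000L; d$end <- d$end + 10000L
  expect_equal(peak_overlap(a, d)$statistic, 0.0)
})

test_that("peak_overlap honours the min-fraction rule in both modes", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  b <- data.frame(chrom = "chr1", start = 40L, end = 240L) # intersection 60
  # 60 >= 0.7 * min(100, 200)? no (70) -> not overlapping
  expect_equal(peak_overlap(a, b, min_frac = 0.7)$n_pairs, 0L)
  expect_equal(peak_overlap(a, b, min_frac = 0.5)$n_pairs, 1L)
  # reciprocal: 60 < 0.5 * 200 -> fails
  expect_equal(peak_overlap(a, b, min_frac = 0.5, mode = "reciprocal")$n_pairs, 0L)
})

test_that("extract_sequence preserves soft-mask case and flips strand", {
  g <- bench_genome(c(chrT = "ACGTacgt"))
  expect_equal(extract_sequence(g, "chrT", 2L, 6L, "+"), "GTac")
  expect_equal(extract_sequence(g, "chrT", 2L, 6L, "-"), "gtAC")
  expect_error(extract_sequence(g, "chrT", 6L, 10L), "out of bounds")
})

test_that("FASTA and narrowPeak round-trips are lossless", {
  g <- small_genome()
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(g, fa)
  g2 <- read_genome_fasta(fa)
  expect_identical(g$seq, g2$seq)
  unlink(fa)

  pk <- data.frame(chrom = c("chr2", "chr1"), start = c(5L, 0L),
                   end = c(25L, 10L), name = c("b", "a"),
                   score = 0L, strand = ".", signal = c(2, 1),
                   pvalue = -1, qvalue = -1, summit = -1L)
  np <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, np)
  rt <- read_narrowpeak(np)
  expect_equal(rt$chrom, c("chr1", "chr2")) # writer sorts
  expect_equal(rt$signal, c(1, 2))
  unlink(np)
})

test_that("window composition agrees with direct sequence counting", {
  g <- small_genome()
  set.seed(7)
  st <- sample.int(g$lengths[["chr1"]] - 300L, 25L)
  comp <- window_composition(g, "chr1", st, st + 300L)
  seqs <- extract_sequences(g, data.frame(chrom = "chr1", start = st,
                                          end = st + 300L))
  expect_equal(comp$gc, gc_fraction(seqs))
  expect_equal(comp$mask_count, masked_count(seqs))
})
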