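test_that("genome generation is deterministic and honours the spec", {
  spec <- genome_spec(chrom_lengths = c(chrA = 1000000L),
                      background_gc = 0.5, gc_rich_island_rate = 0,
                      repeat_fraction = 0.05, seed = 3L)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1$seq, g2$seq)
  # byte-identical FASTA
  f1 <- tempfile(); f2 <- tempfile()
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
  # realized global GC within the contract band (no islands here)
  gc <- window_composition(g1, "chrA", 0L, 1000000L)$gc
  expect_gt(gc, 0.48); expect_lt(gc, 0.52)
  # realized soft-masked fraction close to the requested 0.05
  mk <- window_composition(g1, "chrA", 0L, 1000000L)$mask_count / 1e6
  expect_lt(abs(mk - 0.05), 0.02)
})

test_that("zero repeat fraction gives an unmasked genome", {
  g <- generate_genome(genome_spec(chrom_lengths = c(chrA = 50000L),
                                   repeat_fraction = 0, seed = 5L))
  expect_false(grepl("[a-z]", g$seq[["chrA"]]))
})

test_that("island and repeat truth tables describe the sequence", {
  g <- small_genome()
  isl <- g$islands
  expect_gt(nrow(isl), 0L)
  gcs <- vapply(seq_len(nrow(isl)), function(i)
    window_composition(g, isl$chrom[i], isl$start[i], isl$end[i])$gc, numeric(1))
  expect_gt(mean(gcs), 0.55) # islands really are GC-rich
  rep_ <- g$repeats
  for (i in sample.int(nrow(rep_), 10L)) {
    s <- extract_sequence(g, rep_$chrom[i], rep_$start[i], rep_$end[i])
    expect_equal(masked_count(s), nchar(s)) # fully soft-masked
  }
})

test_that("a chromosome shorter than a repeat block is rejected", {
  expect_error(genome_spec(chrom_lengths = c(chrA = 1200L),
                           repeat_block_length = 2000L,
                           repeat_fraction = 0.1),
               "repeat block")
})

test_that("plant_elements emits the requested peaks with planted motifs", {
  w <- small_world()
  expect_equal(nrow(w$peaks$lineA), 120L)
  expect_equal(nrow(w$peaks$lineB), 120L)
  # truth-table consistency: instances inside their element, elements
  # inside their chromosome
  el <- w$elements
  tr <- w$truth
  m <- match(tr$element_id, el$element_id)
  expect_true(all(tr$start >= el$start[m] & tr$end <= el$end[m]))
  expect_true(all(el$end <= w$genome$lengths[el$chrom]))
  # every emitted peak carries at least the per-line minimum of instances
  counts <- table(tr$element_id)
  expect_true(all(w$peaks$lineA$signal >= 2))
})

test_that("scanning positives recovers planted instances", {
  w <- small_world()
  pos <- peaks_to_records(w$elements, w$genome)
  sc <- scan_motifs(pos$seq, w$library)
  m <- sc$matches
  m$gstart <- pos$start[m$record] + m$start
  m$chrom <- pos$chrom[m$record]
  found <- paste(w$truth$chrom, w$truth$start, w$truth$motif) %in%
    paste(m$chrom, m$gstart, m$motif)
  expect_gte(mean(found), 0.95)
})

test_that("element sharing is controlled and zero sharing means exclusivity", {
  g <- small_genome()
  lib <- random_motif_library(seed = 20L)
  lines <- list(cell_line_model("A", names(lib)[1:3], 40L),
                cell_line_model("B", names(lib)[4:6], 40L))
  pl <- plant_elements(g, lib, lines, shared_fraction = 0, seed = 21L)
  ov <- peak_overlap(pl$peaks$A, pl$peaks$B, min_frac = 0.7)
  expect_equal(ov$n_pairs, 0L)
})

test_that("make_replicate reproduces dropout and jitter statistics", {
  w <- small_world()
  pk <- w$peaks$lineA
  expect_identical(make_replicate(pk, 0, 0, seed = 1L)[, c("start", "end")],
                   pk[, c("start", "end")])
  # binomial survivor count across seeds
  pk1000 <- data.frame(chrom = "chr1", start = seq(0L, 999L) * 350L)
  pk1000$end <- pk1000$start + 300L
  survivors <- vapply(1:200, function(s)
    nrow(make_replicate(pk1000, 0, 0.5, seed = s)), numeric(1))
  se <- sqrt(1000 * 0.25) / sqrt(200) # binomial sd over sqrt(n_seeds)
  expect_lt(abs(mean(survivors) - 500), 3 * se)
  # jitter degrades but does not destroy overlap (at a strict overlap
  # requirement a 5 bp jitter SD moves some peaks out of qualification)
  repj <- make_replicate(pk, jitter_sd = 5, dropout_rate = 0, seed = 2L,
                         chrom_lengths = w$genome$lengths)
  stat <- peak_overlap(pk, repj, min_frac = 0.99)$statistic
  expect_lt(stat, 1.0)
  expect_gt(stat, 0)
})

test_that("activity readouts follow the linear model exactly when noiseless", {
  w <- small_world()
  frag <- peaks_to_records(w$elements[1:60, ], w$genome)
  # sigma = 0, beta_gc = 0: readout is a monotone map of motif density
  a <- simulate_activity(frag, activity_model(0, 10, 0, 0), w$library)
  expect_equal(spearman(a$readout, a$density)$value, 1.0)
  # sigma = 0, beta_density = 0, beta_gc = 1: monotone in GC
  a <- simulate_activity(frag, activity_model(0, 0, 1, 0), w$library)
  expect_equal(spearman(a$readout, a$gc)$value, 1.0)
  # deterministic given the model seed
  a1 <- simulate_activity(frag, activity_model(0, 10, 1, 0.5, seed = 7L), w$library)
  a2 <- simulate_activity(frag, activity_model(0, 10, 1, 0.5, seed = 7L), w$library)
  expect_identical(a1$readout, a2$readout)
})

test_that("overwhelming noise washes out the density signal", {
  w <- small_world()
  set.seed(31)
  idx <- sample(nrow(w$elements), 60L, replace = TRUE)
  frag <- peaks_to_records(w$elements[idx, ], w$genome)
  frag <- rbind(frag, peaks_to_records(random_windows(w$genome, 440L, seed = 32L)[,
    c("chrom", "start", "end")], w$genome))
  a <- simulate_activity(frag, activity_model(0, 10, 0, 1000, seed = 33L),
                         w$library)
  expect_lt(abs(spearman(a$readout, a$density)$value), 0.2)
})

test_that("open-chromatin GC is bimodal with islands, unimodal without", {
  w <- small_world()
  gc_with <- gc_fraction(peaks_to_records(w$elements, w$genome)$seq)
  # two separated modes: mass both below 0.5 and above 0.55
  expect_gt(mean(gc_with > 0.55), 0.08)
  expect_gt(mean(gc_with < 0.50), 0.5)

  g0 <- generate_genome(genome_spec(
    chrom_lengths = c(chr1 = 400000L, chr2 = 300000L),
    gc_rich_island_rate = 0, seed = 41L))
  lib <- random_motif_library(seed = 42L)
  lines <- list(cell_line_model("A", names(lib)[1:3], 60L),
                cell_line_model("B", names(lib)[4:6], 60L))
  pl <- plant_elements(g0, lib, lines, island_element_fraction = 0, seed = 43L)
  gc_wo <- gc_fraction(peaks_to_records(pl$elements, pl$genome)$seq)
  expect_lt(mean(gc_wo > 0.55), 0.02)
})
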