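test_that("chromosome hold-out split is exhaustive and disjoint", {
  rec <- data.frame(id = paste0("r", 1:6),
                    chrom = c("chr21", "chr8", "chrX", "chr1", "chr8", "chr21"),
                    stringsAsFactors = FALSE)
  sp <- chromosome_split(rec)
  expect_equal(sp$validation$id, c("r1", "r6"))
  expect_equal(sp$test$id, c("r2", "r5"))
  expect_equal(sp$train$id, c("r3", "r4")) # gonosomes train
  all_ids <- c(sp$train$id, sp$validation$id, sp$test$id)
  expect_setequal(all_ids, rec$id)
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("tissue-specific sets apply the 30% overlap rule one-sidedly", {
  g <- bench_genome(c(chr8 = strrep("ACGT", 2500), chr21 = strrep("ACGT", 2500)))
  # target peaks: one overlapped 50%, one 20%, one free (mirrored on the
  # validation chromosome so both hold-out splits are populated)
  target <- data.frame(chrom = rep(c("chr8", "chr21"), each = 3L),
                       start = rep(c(0L, 1000L, 2000L), 2L),
                       end = rep(c(100L, 1100L, 2100L), 2L))
  other <- data.frame(chrom = rep(c("chr8", "chr21"), each = 3L),
                      start = rep(c(50L, 1080L, 3000L), 2L),
                      end = rep(c(150L, 1180L, 3100L), 2L))
  sets <- build_tissue_specific_sets(
    list(A = target, B = other), "A", g,
    max_overlap = 0.3, validation_chrom = "chr21", test_chrom = "chr8")
  pos <- sets$test$positives
  expect_equal(sort(pos$start), c(1000L, 2000L)) # 50%-overlap excluded
  neg <- sets$test$negatives
  expect_equal(sort(neg$start), c(1080L, 3000L)) # 50% overlapper excluded
  expect_true(all(pos$label == 1L) && all(neg$label == 0L))
})

test_that("zero sharing makes all target test-chromosome peaks positives", {
  g <- small_genome()
  lib <- random_motif_library(seed = 50L)
  lines <- list(cell_line_model("A", names(lib)[1:3], 80L),
                cell_line_model("B", names(lib)[4:6], 80L))
  pl <- plant_elements(g, lib, lines, shared_fraction = 0, seed = 51L)
  sets <- build_tissue_specific_sets(pl$peaks, "A", pl$genome)
  n_target_test <- sum(pl$peaks$A$chrom == "chr8")
  expect_equal(nrow(sets$test$positives), n_target_test)
})

test_that("tissue-specific sets never contain training-chromosome records", {
  w <- small_world()
  sets <- build_tissue_specific_sets(w$peaks, "lineA", w$genome)
  for (split in sets) {
    expect_true(all(split$positives$chrom %in% c("chr8", "chr21")))
    expect_true(all(split$negatives$chrom %in% c("chr8", "chr21")))
  }
  expect_true(all(sets$validation$positives$chrom == "chr21"))
  expect_true(all(sets$test$positives$chrom == "chr8"))
})

test_that("merged set ladders are nested, sized and deterministic", {
  w <- small_world()
  peaks <- list(A = w$peaks$lineA, B = w$peaks$lineB)
  sizes <- c(40L, 80L, 160L, 240L)
  m1 <- build_merged_sets(peaks, 120L, sizes, seed = 52L)
  expect_equal(vapply(m1, nrow, integer(1)),
               setNames(sizes, as.character(sizes)))
  key <- function(d) paste(d$chrom, d$start, d$end, d$name)
  for (i in 1:3)
    expect_true(all(key(m1[[i]]) %in% key(m1[[i + 1L]])))
  m2 <- build_merged_sets(peaks, 120L, sizes, seed = 52L)
  expect_identical(m1, m2)
  expect_error(build_merged_sets(peaks, 500L, c(100L, 1000L)),
               "insufficient")
  expect_error(build_merged_sets(peaks, 100L, c(50L, 150L)),
               "largest size")
})

test_that("activity fragments are centered, extended and filtered", {
  g <- small_genome()
  ft <- data.frame(chrom = "chr1",
                   start = c(10000L, 20000L, 30000L, 0L),
                   end = c(10171L, 20171L, 30300L, 171L),
                   length = c(171L, 170L, 300L, 171L),
                   readout = c(1.5, 2.5, -0.5, 3.5))
  suppressMessages(rec <- prepare_activity_fragments(ft, g))
  # row 2 dropped (stated length disagrees), row 4 dropped (overflow)
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "dropped")[["length_mismatch"]], 1L)
  expect_equal(attr(rec, "dropped")[["chromosome_overflow"]], 1L)
  expect_equal(rec$end - rec$start, c(300L, 300L))
  # 171 bp fragment: center preserved under the floor rule
  expect_equal((rec$start[1] + rec$end[1]) %/% 2L, (10000L + 10171L) %/% 2L)
  # already-300 bp fragment is a fixed point
  expect_equal(rec$start[2], 30000L)
  expect_equal(rec$readout, c(1.5, -0.5))
})

test_that("balanced datasets drop unmatched positives to stay 1:1", {
  pos <- data.frame(id = paste0("p", 1:5), chrom = "chr1",
                    start = 1:5 * 1000L, end = 1:5 * 1000L + 300L,
                    strand = "+", seq = "ACGT", label = 1L,
                    stringsAsFactors = FALSE)
  neg <- pos[1:3, ]
  neg$id <- paste0(neg$id, "_bg"); neg$label <- 0L
  neg$paired_positive <- pos$id[1:3]
  ds <- balanced_dataset(pos, neg)
  expect_equal(sum(ds$label == 1L), 3L)
  expect_equal(sum(ds$label == 0L), 3L)
  expect_equal(attr(ds, "n_dropped_positives"), 2L)
})

test_that("assembled experiments have no train/evaluation leakage", {
  w <- small_world()
  pos <- peaks_to_records(w$peaks$lineA, w$genome, cell_line = "lineA")
  sp <- chromosome_split(pos)
  ids <- c(sp$train$id, sp$validation$id, sp$test$id)
  expect_equal(anyDuplicated(ids), 0L)
  expect_length(intersect(sp$train$id, c(sp$validation$id, sp$test$id)), 0L)
  expect_false(any(sp$train$chrom %in% c("chr8", "chr21")))
})
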