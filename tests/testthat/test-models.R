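test_that("featurization counts every window-mask token", {
  cfg10 <- gkm_config(l = 10L, k = 6L, reverse_complement_collapse = FALSE,
                      normalization = "none")
  x <- gkm_featurize("ACGTACGTAC", cfg10) # one window
  expect_equal(sum(x), choose(10, 6))
  expect_equal(dim(x), c(1L, choose(10, 6) * 4^6))
  # total token count is (L - l + 1) * C(l, k) regardless of content
  cfg <- gkm_config(l = 6L, k = 4L, reverse_complement_collapse = FALSE)
  set.seed(1)
  for (L in c(6L, 30L, 101L)) {
    s <- random_dna(L)
    expect_equal(sum(gkm_featurize(s, cfg)), (L - 6 + 1) * choose(6, 4))
  }
})

test_that("l = k featurization equals plain k-mer counting", {
  cfg <- gkm_config(l = 5L, k = 5L, reverse_complement_collapse = FALSE,
                    normalization = "none")
  set.seed(2)
  s <- random_dna(80)
  x <- gkm_featurize(s, cfg)
  oracle <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), 5L)
  # single mask: feature order is code order = lexicographic A<C<G<T
  expect_equal(as.numeric(x), as.numeric(oracle))
})

test_that("reverse-complement collapse makes featurization strand-blind", {
  cfg <- gkm_config(l = 6L, k = 4L, reverse_complement_collapse = TRUE)
  set.seed(3)
  for (i in 1:5) {
    s <- random_dna(50)
    expect_equal(gkm_featurize(s, cfg), gkm_featurize(rev_comp(s), cfg))
  }
  # collapsing at most halves the observed distinct tokens
  s <- random_dna(200)
  n_collapsed <- Matrix::nnzero(gkm_featurize(s, cfg))
  cfg_off <- gkm_config(l = 6L, k = 4L, reverse_complement_collapse = FALSE)
  n_full <- Matrix::nnzero(gkm_featurize(s, cfg_off))
  expect_gte(n_collapsed, n_full / 2)
  expect_lte(n_collapsed, n_full)
})

test_that("short sequences produce empty rows with a warning", {
  cfg <- gkm_config(l = 10L, k = 6L)
  expect_warning(x <- gkm_featurize(c("ACGT", "ACGTACGTACGT"), cfg), "shorter")
  expect_equal(Matrix::nnzero(x[1L, , drop = FALSE]), 0L)
  expect_gt(Matrix::nnzero(x[2L, , drop = FALSE]), 0L)
})

test_that("a planted-word problem is learned almost perfectly", {
  set.seed(4)
  word <- "GATAAG"
  mk_pos <- function() {
    s <- random_dna(60)
    at <- sample(1:(60 - 6), 2L)
    for (a in at) substr(s, a, a + 5L) <- word
    s
  }
  pos <- vapply(1:250, function(i) mk_pos(), character(1))
  neg <- vapply(pos, function(s) kmer_shuffle(s, 1L), character(1),
                USE.NAMES = FALSE)
  cfg <- gkm_config(l = 6L, k = 4L)
  fit <- train_gkm(pos[1:200], neg[1:200], cfg)
  sc <- predict(fit, c(pos[201:250], neg[201:250]))
  y <- rep(1:0, each = 50L)
  expect_gte(auroc(sc, y)$value, 0.9)
  # label flip symmetry on the same hold-out
  fit_fl <- train_gkm(neg[1:200], pos[1:200], cfg)
  sc_fl <- predict(fit_fl, c(pos[201:250], neg[201:250]))
  expect_equal(auroc(sc_fl, y)$value, 1 - auroc(sc, y)$value, tolerance = 1e-6)
  # duplicating the training set preserves the fitted ranking
  fit_dup <- train_gkm(rep(pos[1:200], 2L), rep(neg[1:200], 2L), cfg)
  sc_dup <- predict(fit_dup, c(pos[201:250], neg[201:250]))
  expect_gte(cor(rank(sc), rank(sc_dup)), 0.99)
  # margins of a lightly-regularised fit on this separable problem
  # separate the classes completely on the training data
  fit_sep <- train_gkm(pos[1:200], neg[1:200], cfg, lambda = 1e-4)
  m <- predict(fit_sep, c(pos[1:200], neg[1:200]), type = "margin")
  expect_gt(min(m[1:200]), max(m[201:400]))
})

test_that("degenerate training inputs are rejected", {
  set.seed(5)
  seqs <- vapply(1:20, function(i) random_dna(30), character(1))
  expect_error(train_gkm(seqs, character(0)), "at least 10")
  expect_error(train_gkm(seqs[1:5], seqs[6:20]), "at least 10")
})

test_that("prediction is deterministic, monotone-invariant and empty-safe", {
  set.seed(6)
  pos <- vapply(1:30, function(i) random_dna(40, gc = 0.7), character(1))
  neg <- vapply(1:30, function(i) random_dna(40, gc = 0.3), character(1))
  fit <- train_gkm(pos, neg, gkm_config(l = 5L, k = 3L))
  sc1 <- predict(fit, pos)
  expect_identical(sc1, predict(fit, pos))
  expect_true(all(sc1 > 0 & sc1 < 1))
  mg <- predict(fit, pos, type = "margin")
  expect_equal(rank(mg), rank(sc1)) # logistic link is monotone
  expect_length(predict(fit, character(0)), 0L)
})

test_that("replicate training selects the median performer", {
  # deterministic learner: all replicates identical, first selected
  r <- train_replicates(function(seed) list(w = 1), function(m) 0.7,
                        n_replicates = 5L)
  expect_equal(r$selected, 1L)
  # explicit metrics via a stub learner
  vals <- c(0.6, 0.8, 0.7)
  r <- train_replicates(function(seed) list(seed = seed),
                        function(m) vals[m$seed], n_replicates = 3L, seed = 1L)
  expect_equal(r$selected, 3L) # metric 0.7 is the median
  expect_equal(r$metrics, vals)
  r1 <- train_replicates(function(seed) "m", function(m) 0.5, n_replicates = 1L)
  expect_equal(r1$selected, 1L)
})
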