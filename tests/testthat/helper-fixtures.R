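# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# random DNA string at uniform composition
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a small genome with islands and repeats, fast to build
small_genome <- function() {
  fixture("small_genome", function() {
    generate_genome(genome_spec(
      chrom_lengths = c(chr1 = 400000L, chr2 = 400000L,
                        chr8 = 250000L, chr21 = 200000L),
      seed = 11L))
  })
}

# a small planted world: genome + library + 2 lines with sharing
small_world <- function() {
  fixture("small_world", function() {
    g <- small_genome()
    lib <- random_motif_library(seed = 12L)
    lines <- list(
      cell_line_model("lineA", names(lib)[1:4], 120L),
      cell_line_model("lineB", names(lib)[c(1, 2, 5, 6)], 120L))
    pl <- plant_elements(g, lib, lines, shared_fraction = 0.3,
                         island_element_fraction = 0.15, seed = 13L)
    pl$library <- lib
    pl$lines <- lines
    pl
  })
}

# brute-force k-mer multiset equality
same_kmer_multiset <- function(a, b, k) {
  identical(sort(kmer_strings(a, k)), sort(kmer_strings(b, k)))
}

# exhaustive set of valid k=2 shuffles of a string: all distinct
# arrangements of its letters with identical 2-mer counts and endpoints
valid_shuffles_k2 <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  perms <- fixture(paste0("perm", n), function() .permutations(n))
  chmat <- matrix(ch[perms], nrow = nrow(perms))
  perm_strings <- unique(do.call(paste0, as.data.frame(chmat)))
  keep <- vapply(perm_strings, same_kmer_multiset, logical(1), b = s, k = 2L)
  sort(perm_strings[keep])
}

# all permutations of seq_len(n) as a matrix (n <= 7)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# brute-force AUROC by pair enumeration (ties count 1/2)
pairwise_auroc <- function(scores, labels) {
  ps <- scores[labels == 1L]; ns <- scores[labels == 0L]
  tot <- 0
  for (p in ps) for (q in ns)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

# brute-force AUPRC: step curve evaluated at every distinct threshold
sweep_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  recall <- precision <- numeric(length(thr))
  n_pos <- sum(labels == 1L)
  for (i in seq_along(thr)) {
    sel <- scores >= thr[i]
    recall[i] <- sum(labels[sel] == 1L) / n_pos
    precision[i] <- sum(labels[sel] == 1L) / sum(sel)
  }
  sum(precision * diff(c(0, recall)))
}
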