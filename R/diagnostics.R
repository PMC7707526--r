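#' Sequence-composition diagnostics
#'
#' Genome-wide k-mer frequency Z-scores, PWM motif-density scanning and
#' GC-content distributions — the analyses that explain *why* negative
#' set construction moves model performance.
#' @name diagnostics
NULL

#' Genome k-mer frequency table with Z-scores
#'
#' Counts every overlapping k-window on the forward strand of every
#' chromosome (windows containing non-ACGT characters are skipped;
#' case-folded first), with all 4^k entries present, then Z-transforms
#' the counts (mean-centered, SD normalised to 1).
#'
#' @param genome a [bench_genome()] or named character vector of
#'   sequences
#' @param k word size (default 8: 65,536 entries)
#' @param collapse if `TRUE`, also fold each word onto its reverse
#'   complement before counting (off by default; forward-strand counting
#'   is the reference behaviour)
#' @return object of class `kmer_freq_table`: list with `k`, `counts`
#'   (named, all 4^k words) and `z` (same index space, mean 0, SD 1)
#' @export
build_kmer_table <- function(genome, k = 8L, collapse = FALSE) {
  seqs <- if (inherits(genome, "bench_genome")) genome$seq else genome
  x <- Biostrings::DNAStringSet(toupper(seqs))
  counts <- colSums(Biostrings::oligonucleotideFrequency(x, width = k))
  if (collapse) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(names(counts))))
    counts <- counts + counts[rc]
  }
  z <- (counts - mean(counts)) / sd(counts)
  structure(list(k = as.integer(k), counts = counts, z = z),
            class = "kmer_freq_table")
}

#' @export
print.kmer_freq_table <- function(x, ...) {
  cat(sprintf("<kmer_freq_table> k = %d, %d entries, total count %s\n",
              x$k, length(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

# numeric indices (1-based) of the overlapping k-mers of one sequence;
# NA where the window contains a non-ACGT character
.kmer_indices <- function(s, k) {
  codes <- seq_codes(toupper(s)) - 1L
  L <- length(codes)
  if (L < k) return(numeric(0))
  idx <- numeric(L - k + 1L)
  for (j in 1:k) {
    idx <- idx + codes[j:(L - k + j)] * 4^(k - j)
  }
  idx + 1
}

#' Genome-frequency Z-scores of the k-mers in each sequence
#'
#' For every record, looks up the genome-frequency Z-score of each of its
#' overlapping k-mers and summarises per record and overall. Used to show
#' that shuffled negatives are built from genome-rare words while
#' genomic-background negatives are built from genome-common ones.
#'
#' @param seqs character vector of sequences
#' @param table a [build_kmer_table()] result
#' @return list with `per_record_mean` (mean Z per record, NA for records
#'   shorter than k), `mean_z` (grand mean over all windows) and `n_windows`
#' @export
sequence_kmer_zscores <- function(seqs, table) {
  k <- table$k
  z <- unname(table$z)
  per <- rep(NA_real_, length(seqs))
  tot <- 0; n_tot <- 0L
  for (i in seq_along(seqs)) {
    idx <- .kmer_indices(seqs[i], k)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) {
      if (nchar(seqs[i]) < k)
        warning("record ", i, " shorter than k = ", k)
      next
    }
    zi <- z[idx]
    per[i] <- mean(zi)
    tot <- tot + sum(zi)
    n_tot <- n_tot + length(zi)
  }
  list(per_record_mean = per,
       mean_z = if (n_tot) tot / n_tot else NA_real_,
       n_windows = n_tot)
}

#' Motif scan configuration
#'
#' The match threshold is the smallest log-odds score whose exact
#' p-value under the background base distribution — computed by dynamic
#' programming over the discretised PWM score distribution — is at most
#' `p_value`. This reproduces the semantics of p-value-thresholded PWM
#' scanners without importing one.
#'
#' @param p_value score threshold p-value (default 1e-4)
#' @param background length-4 base distribution (default uniform)
#' @param pseudocount added to PWM probabilities before log-odds
#' @param max_matches retention cap on reported matches (default 500000)
#' @param score_scale discretisation: log-odds scores are rounded to
#'   1/`score_scale` bits
#' @return a `motif_scan_config`
#' @export
motif_scan_config <- function(p_value = 1e-4,
                              background = rep(0.25, 4),
                              pseudocount = 0.01,
                              max_matches = 500000L,
                              score_scale = 100L) {
  stopifnot(p_value > 0, p_value < 1, length(background) == 4L,
            all(background > 0), max_matches >= 1L)
  background <- background / sum(background)
  structure(list(p_value = p_value, background = background,
                 pseudocount = pseudocount,
                 max_matches = as.integer(max_matches),
                 score_scale = as.integer(score_scale)),
            class = "motif_scan_config")
}

# integer log-odds matrix (width x 4) and the p_value score threshold,
# both on the discretised scale
.pwm_threshold <- function(motif, config) {
  p <- motif$matrix
  w <- log2((p + config$pseudocount) /
            matrix(config$background, nrow(p), 4L, byrow = TRUE) /
            (1 + 4 * config$pseudocount))
  wi <- round(w * config$score_scale)
  off <- -apply(wi, 1L, min)
  shifted <- wi + off # non-negative per row
  # DP over the exact score distribution under the background
  dist <- 1
  for (r in seq_len(nrow(shifted))) {
    m <- max(shifted[r, ])
    step <- numeric(m + 1L)
    for (b in 1:4) step[shifted[r, b] + 1L] <- step[shifted[r, b] + 1L] +
        config$background[b]
    dist <- convolve(dist, rev(step), type = "open")
  }
  dist[dist < 0] <- 0 # FFT round-off
  tail_p <- rev(cumsum(rev(dist)))
  # smallest shifted score with P(S >= s) <= p_value
  idx <- which(tail_p <= config$p_value + 1e-12)
  thr_shifted <- if (length(idx)) idx[1L] - 1L else length(dist)
  list(wi = wi, threshold = thr_shifted - sum(off))
}

# integer window scores of `codes` (1..4, NA for non-ACGT) against wi
.scan_scores <- function(codes, wi) {
  width <- nrow(wi)
  L <- length(codes)
  if (L < width) return(numeric(0))
  n <- L - width + 1L
  sc <- numeric(n)
  for (j in seq_len(width)) {
    v <- wi[j, ][codes[j:(n + j - 1L)]]
    sc <- sc + v
  }
  sc # NA propagates through windows containing non-ACGT
}

#' Scan sequences for PWM motif matches
#'
#' Both strands are scanned with the log-odds matrix against the
#' configured background; matches at or above the p-value-derived
#' threshold are reported with position, strand and score. The summary
#' normalises total matches to a per-300-bp rate.
#'
#' @param seqs character vector of sequences (or records with `seq`)
#' @param motif_library a `motif_library`
#' @param config a [motif_scan_config()]
#' @return list with `matches` (data.frame: record, motif, start
#'   (0-based), strand, score in bits), `per_record_hits`,
#'   `motifs_per_300bp` (mean and sd over records of per-record hits
#'   scaled to 300 bp) and `total_rate` (total hits / (total bp / 300))
#' @export
scan_motifs <- function(seqs, motif_library, config = motif_scan_config()) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  pre <- lapply(motif_library, .pwm_threshold, config = config)
  n <- length(seqs)
  per_hits <- integer(n)
  matches <- list()
  n_retained <- 0L
  capped <- FALSE
  motif_names <- names(motif_library)
  for (i in seq_len(n)) {
    codes <- seq_codes(toupper(seqs[i]))
    L <- length(codes)
    rc_codes <- rev(5L - codes) # A<->T, C<->G on reversed sequence
    for (mi in seq_along(motif_library)) {
      wi <- pre[[mi]]$wi
      width <- nrow(wi)
      if (L < width) next # motif wider than sequence: skipped
      thr <- pre[[mi]]$threshold
      for (strand in c("+", "-")) {
        sc <- .scan_scores(if (strand == "+") codes else rc_codes, wi)
        hit <- which(!is.na(sc) & sc >= thr)
        if (!length(hit)) next
        per_hits[i] <- per_hits[i] + length(hit)
        if (n_retained < config$max_matches) {
          st <- if (strand == "+") hit - 1L else L - (hit - 1L) - width
          matches[[length(matches) + 1L]] <- data.frame(
            record = i, motif = motif_names[mi], start = st, strand = strand,
            score = sc[hit] / config$score_scale, stringsAsFactors = FALSE)
          n_retained <- n_retained + length(hit)
        } else capped <- TRUE
      }
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(record = integer(), motif = character(), start = integer(),
               strand = character(), score = numeric())
  rownames(matches) <- NULL
  widths <- nchar(seqs)
  rate_per_rec <- if (n) per_hits / widths * 300 else numeric(0)
  list(matches = matches,
       per_record_hits = per_hits,
       motifs_per_300bp = c(mean = if (n) mean(rate_per_rec) else NA_real_,
                            sd = if (n > 1) sd(rate_per_rec) else NA_real_),
       total_rate = if (sum(widths)) sum(per_hits) / (sum(widths) / 300)
                    else NA_real_,
       capped = capped)
}

#' Random fixed-width windows from a genome
#'
#' Reference sample for the genome's base composition.
#' @param genome a [bench_genome()]
#' @param n number of windows
#' @param width window width in bp (default 300)
#' @param seed integer seed
#' @return data.frame of records with coordinates and sequences
#' @export
random_windows <- function(genome, n, width = 300L, seed = 1L) {
  chroms <- names(genome$seq)
  valid <- pmax(genome$lengths - width + 1L, 0L)
  if (sum(valid) == 0L) stop("no chromosome can hold a window of width ", width)
  with_seed(seed, {
    ci <- sample.int(length(chroms), n, replace = TRUE, prob = valid / sum(valid))
    st <- as.integer(floor(runif(n) * valid[ci]))
  })
  d <- data.frame(id = sprintf("rw%06d", seq_len(n)),
                  chrom = chroms[ci], start = st, end = st + as.integer(width),
                  strand = "+", stringsAsFactors = FALSE)
  d$seq <- extract_sequences(genome, d)
  d
}

#' Per-sequence GC content and distribution comparisons
#'
#' GC = (G+C)/length, case-insensitive; histogram at `bin_width`
#' resolution; two-sample KS statistics for any named pairs of sets.
#'
#' @param sets named list of character vectors of sequences (or record
#'   data.frames with `seq`)
#' @param bin_width histogram bin width (default 0.01)
#' @param ks_pairs optional list of length-2 character vectors naming
#'   set pairs to compare
#' @return list with `gc` (named list of per-sequence GC vectors),
#'   `histograms` (named list of data.frames bin_low/count) and `ks`
#'   (named numeric vector of KS statistics)
#' @export
gc_distribution <- function(sets, bin_width = 0.01, ks_pairs = NULL) {
  gc <- lapply(sets, function(s) {
    if (is.data.frame(s)) s <- s$seq
    gc_fraction(s)
  })
  breaks <- seq(0, 1, by = bin_width)
  histograms <- lapply(gc, function(g) {
    b <- cut(g, breaks = breaks, right = FALSE, include.lowest = TRUE)
    data.frame(bin_low = head(breaks, -1L), count = as.integer(table(b)))
  })
  ks <- numeric(0)
  if (!is.null(ks_pairs)) {
    ks <- vapply(ks_pairs, function(p)
      ks_statistic(gc[[p[1]]], gc[[p[2]]]), numeric(1))
    names(ks) <- vapply(ks_pairs, paste, "", collapse = "_vs_")
  }
  list(gc = gc, histograms = histograms, ks = ks)
}
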