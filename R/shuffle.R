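#' k-mer-count-preserving sequence shuffling
#'
#' Negative training sequences can be built by shuffling each positive
#' sequence while preserving its exact k-mer counts. For k >= 2 this is
#' realised as a random Eulerian path on the de Bruijn graph whose
#' vertices are the sequence's (k-1)-mers and whose edges are its k-mers
#' (Altschul-Erickson): a uniform random arborescence toward the terminal
#' vertex (Wilson's algorithm) guarantees the walk consumes every edge,
#' and randomised edge orderings randomise the path. Every output
#' therefore has exactly the input's k-mer multiset, and the first and
#' last (k-1)-mers equal the input's. k = 1 is a uniform permutation of
#' the letters.
#' @name shuffling
NULL

#' Shuffle configuration for negative-set generation
#'
#' @param k preserved k-mer size (>= 1; 1..7 is the usual sweep)
#' @param n_candidates shuffles generated per positive sequence; the one
#'   with minimal `overlap_k`-mer overlap to the original is kept
#'   (default 200)
#' @param overlap_k word size for the overlap score (default 8)
#' @param multiset if `TRUE` score shared k-mers with multiplicity instead
#'   of as distinct types
#' @param seed integer seed; per-record streams are derived from it
#' @return a `shuffle_config` list
#' @export
shuffle_config <- function(k = 2L, n_candidates = 200L, overlap_k = 8L,
                           multiset = FALSE, seed = 1L) {
  stopifnot(k >= 1L, n_candidates >= 1L, overlap_k >= 1L)
  structure(list(k = as.integer(k), n_candidates = as.integer(n_candidates),
                 overlap_k = as.integer(overlap_k), multiset = multiset,
                 seed = as.integer(seed)),
            class = "shuffle_config")
}

#' All overlapping k-mers of a sequence
#' @param x character string
#' @param k word size
#' @return character vector of `nchar(x) - k + 1` words (empty when the
#'   sequence is shorter than k)
#' @export
kmer_strings <- function(x, k) {
  L <- nchar(x)
  if (L < k) return(character(0))
  substring(x, 1:(L - k + 1L), k:L)
}

#' Shuffle a sequence preserving its k-mer counts
#'
#' Uses the current RNG stream (wrap in [with_seed()] or `set.seed()` for
#' reproducibility). Input case is folded to uppercase: soft-masking is
#' meaningless after shuffling.
#'
#' @param x a DNA string over A,C,G,T (case-insensitive)
#' @param k preserved k-mer size, `1 <= k <= nchar(x)`
#' @return a shuffled string with exactly the same k-mer multiset
#' @export
kmer_shuffle <- function(x, k) {
  s <- toupper(x)
  L <- nchar(s)
  if (k < 1L || k > L) stop("k must be in [1, nchar(x)]")
  if (grepl("[^ACGT]", s)) stop("kmer_shuffle: sequence contains non-ACGT characters")
  if (k == 1L) {
    return(paste(sample(strsplit(s, "")[[1]]), collapse = ""))
  }
  if (L == k) return(s)
  n <- L - k + 1L # edges
  verts <- substring(s, 1:(n + 1L), (k - 1L):(L)) # (k-1)-mers
  uv <- unique(verts)
  ids <- match(verts, uv) - 1L
  labels <- strsplit(substr(s, k, L), "")[[1]]
  path <- cpp_euler_walk(ids[1:n], ids[2:(n + 1L)], length(uv),
                         ids[1L], ids[n + 1L])
  paste0(substr(s, 1L, k - 1L), paste(labels[path], collapse = ""))
}

#' Generate candidate shuffles and keep the least-overlapping one
#'
#' Draws `n_candidates` k-mer-preserving shuffles and returns the one
#' sharing the fewest distinct `overlap_k`-mers with the original (ties
#' broken by lowest candidate index). Sequences shorter than `overlap_k`
#' score 0 for every candidate, so candidate 0 is returned.
#'
#' @param x positive DNA sequence
#' @param config a [shuffle_config()]
#' @param record_id identifier used to derive this record's RNG stream
#'   from `config$seed`; defaults to the sequence itself
#' @return list with `sequence`, `score`, `index` (1-based candidate
#'   index) and `scores` for all candidates
#' @export
select_min_overlap_shuffle <- function(x, config = shuffle_config(),
                                       record_id = NULL) {
  if (is.null(record_id)) record_id <- x
  orig <- toupper(x)
  orig_kmers <- kmer_strings(orig, config$overlap_k)
  orig_tab <- if (config$multiset) table(orig_kmers) else NULL
  orig_set <- unique(orig_kmers)
  with_seed(derive_seed(config$seed, record_id), {
    cands <- character(config$n_candidates)
    scores <- numeric(config$n_candidates)
    for (i in seq_len(config$n_candidates)) {
      cands[i] <- kmer_shuffle(x, config$k)
      kc <- kmer_strings(cands[i], config$overlap_k)
      scores[i] <- if (!length(orig_set)) 0L
      else if (config$multiset) {
        tc <- table(kc)
        common <- intersect(names(tc), names(orig_tab))
        sum(pmin(tc[common], orig_tab[common]))
      } else sum(unique(kc) %in% orig_set)
    }
    best <- which.min(scores) # first minimum = lowest index
    list(sequence = cands[best], score = scores[best], index = best,
         scores = scores)
  })
}

#' Build a shuffle negative set for a table of positive records
#'
#' One negative per positive, generated by [select_min_overlap_shuffle()]
#' with a per-record RNG stream derived from `(config$seed, id)`, so
#' results do not depend on processing order. Negatives inherit the
#' positive's coordinates (used only for chromosome hold-out splitting)
#' and carry `label = 0` and a `neg_type` of the form `"shuffle_k<k>"`.
#'
#' @param records data.frame of positive records with columns `id`,
#'   `chrom`, `start`, `end`, `seq`
#' @param config a [shuffle_config()]
#' @return data.frame of negative records (one per positive), with an
#'   `overlap_score` column reporting the selected candidate's score
#' @export
make_shuffle_negatives <- function(records, config = shuffle_config()) {
  n <- nrow(records)
  seqs <- character(n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    res <- select_min_overlap_shuffle(records$seq[i], config,
                                      record_id = records$id[i])
    seqs[i] <- res$sequence
    scores[i] <- res$score
  }
  data.frame(id = paste0(records$id, "_shufk", config$k),
             chrom = records$chrom, start = records$start, end = records$end,
             strand = if ("strand" %in% names(records)) records$strand else "+",
             seq = seqs, label = 0L,
             cell_line = if ("cell_line" %in% names(records)) records$cell_line else NA,
             neg_type = paste0("shuffle_k", config$k),
             paired_positive = records$id,
             overlap_score = scores,
             stringsAsFactors = FALSE)
}
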