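#' Dataset assembly: splits, tissue-specific sets, merged sets
#'
#' Record tables carry one sequence per row with columns `id`, `chrom`,
#' `start`, `end`, `strand`, `seq`, `label` (1/0) and provenance
#' (`cell_line`, `neg_type`). Splitting is by whole chromosomes so no
#' positional leakage between training and evaluation is possible.
#' @name datasets
NULL

#' Make a record table from peaks
#'
#' @param peaks data.frame of intervals (`chrom`, `start`, `end`,
#'   optionally `name`)
#' @param genome a [bench_genome()] to extract sequences from
#' @param label class label (1 positive, 0 negative)
#' @param cell_line,neg_type provenance strings
#' @return record data.frame
#' @export
peaks_to_records <- function(peaks, genome, label = 1L, cell_line = NA,
                             neg_type = NA) {
  n <- nrow(peaks)
  d <- data.frame(
    id = if ("name" %in% names(peaks)) peaks$name
         else sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end),
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    strand = "+", stringsAsFactors = FALSE)
  d$seq <- toupper(extract_sequences(genome, d))
  d$label <- as.integer(label)
  d$cell_line <- cell_line
  d$neg_type <- neg_type
  d
}

#' Chromosome hold-out split
#'
#' Validation and test sets are whole-chromosome hold-outs; everything
#' else — remaining autosomes and the sex chromosomes — trains.
#'
#' @param records record data.frame with a `chrom` column
#' @param validation_chrom held-out validation chromosome
#'   (default `"chr21"`)
#' @param test_chrom held-out test chromosome (default `"chr8"`)
#' @return named list of record data.frames: `train`, `validation`,
#'   `test` (an exhaustive, disjoint partition)
#' @export
chromosome_split <- function(records, validation_chrom = "chr21",
                             test_chrom = "chr8") {
  val <- records$chrom == validation_chrom
  tst <- records$chrom == test_chrom
  out <- list(train = records[!val & !tst, , drop = FALSE],
              validation = records[val, , drop = FALSE],
              test = records[tst, , drop = FALSE])
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Tissue-specific positive and negative test sets
#'
#' Positives are the target line's peaks overlapped at most
#' `max_overlap` (as a fraction of the peak's own length) by any other
#' line's peaks; negatives are the other lines' peaks overlapped at most
#' `max_overlap` by the target line. These sets are for evaluation only:
#' output is restricted to the validation and test hold-out chromosomes
#' and never includes training chromosomes.
#'
#' @param peak_sets_by_line named list of peak data.frames (centered and
#'   resized already)
#' @param target_line name of the line under consideration
#' @param genome a [bench_genome()] for sequence extraction
#' @param max_overlap tolerated overlap fraction (default 0.3)
#' @param validation_chrom,test_chrom hold-out chromosomes
#' @return list with `validation` and `test`, each a list of `positives`
#'   and `negatives` record data.frames
#' @export
build_tissue_specific_sets <- function(peak_sets_by_line, target_line, genome,
                                       max_overlap = 0.3,
                                       validation_chrom = "chr21",
                                       test_chrom = "chr8") {
  if (length(peak_sets_by_line) < 2L)
    stop("need at least two cell lines")
  if (!target_line %in% names(peak_sets_by_line))
    stop("unknown target line: ", target_line)
  target <- peak_sets_by_line[[target_line]]
  others <- do.call(rbind, lapply(
    setdiff(names(peak_sets_by_line), target_line),
    function(ln) peak_sets_by_line[[ln]][, c("chrom", "start", "end")]))
  # drop coordinate duplicates among the other lines (shared elements)
  others <- unique(others)

  cov_t <- interval_covered_by(target, others)
  pos <- target[cov_t <= max_overlap * (target$end - target$start), ,
                drop = FALSE]
  cov_o <- interval_covered_by(others, target)
  neg <- others[cov_o <= max_overlap * (others$end - others$start), ,
                drop = FALSE]

  out <- list()
  for (split in c("validation", "test")) {
    chrom <- if (split == "validation") validation_chrom else test_chrom
    p <- pos[pos$chrom == chrom, , drop = FALSE]
    n <- neg[neg$chrom == chrom, , drop = FALSE]
    if (nrow(p) == 0L)
      stop("no tissue-specific positives for ", target_line, " on ", chrom)
    if (nrow(n) == 0L)
      stop("no tissue-specific negatives for ", target_line, " on ", chrom)
    out[[split]] <- list(
      positives = peaks_to_records(p, genome, label = 1L,
                                   cell_line = target_line,
                                   neg_type = "tissue_positive"),
      negatives = peaks_to_records(n, genome, label = 0L,
                                   cell_line = target_line,
                                   neg_type = "tissue_negative"))
  }
  out
}

#' Merged multi-line datasets of graded sizes
#'
#' Draws `per_line_n` peaks from every line into one pool, then builds a
#' nested ladder of subsets: each smaller set is sampled from (and is a
#' subset of) the next larger one, mirroring size-gradation by
#' subsampling from the largest merged set.
#'
#' @param peak_sets_by_line named list of peak data.frames
#' @param per_line_n peaks drawn per line (error if any line has fewer)
#' @param sizes increasing integer vector of total set sizes; the
#'   largest must equal `per_line_n * n_lines`
#' @param seed integer seed
#' @return named list of peak data.frames, one per size (names are the
#'   sizes), nested by construction
#' @export
build_merged_sets <- function(peak_sets_by_line, per_line_n, sizes, seed = 1L) {
  avail <- vapply(peak_sets_by_line, nrow, integer(1))
  if (any(avail < per_line_n))
    stop("insufficient peaks: need ", per_line_n, " per line, have ",
         paste(sprintf("%s=%d", names(avail), avail), collapse = ", "))
  sizes <- sort(unique(as.integer(sizes)))
  if (max(sizes) != per_line_n * length(peak_sets_by_line))
    stop("largest size must equal per_line_n * number of lines")
  with_seed(seed, {
    pool <- do.call(rbind, lapply(names(peak_sets_by_line), function(ln) {
      d <- peak_sets_by_line[[ln]]
      d <- d[sample.int(nrow(d), per_line_n), , drop = FALSE]
      d$source_line <- ln
      d
    }))
    rownames(pool) <- NULL
    out <- list()
    current <- pool
    for (s in rev(sizes)) {
      current <- current[sample.int(nrow(current), s), , drop = FALSE]
      rownames(current) <- NULL
      out[[as.character(s)]] <- current
    }
  })
  out[order(as.integer(names(out)))]
}

#' Prepare activity fragments at a fixed width
#'
#' Fragments are symmetrically extended (center floored) to
#' `target_width`; rows whose recorded `length` disagrees with the
#' coordinate span are excluded, as are fragments that would extend past
#' a chromosome end. The readout column is carried through unchanged.
#'
#' @param fragment_table data.frame with `chrom`, `start`, `end`,
#'   optionally `length`, and a `readout` column
#' @param genome a [bench_genome()]
#' @param target_width final fragment width (default 300)
#' @return record data.frame with `readout`, plus attribute `dropped`
#'   (named counts per drop reason)
#' @export
prepare_activity_fragments <- function(fragment_table, genome,
                                       target_width = 300L) {
  x <- fragment_table
  n_len_bad <- 0L
  if ("length" %in% names(x)) {
    len_bad <- x$length != (x$end - x$start)
    n_len_bad <- sum(len_bad)
    x <- x[!len_bad, , drop = FALSE]
  }
  resized <- center_and_resize(x, width = target_width,
                               chrom_lengths = genome$lengths)
  n_overflow <- nrow(attr(resized, "dropped"))
  rec <- peaks_to_records(resized[, c("chrom", "start", "end")], genome,
                          label = 1L, neg_type = "activity_fragment")
  rec$readout <- resized$readout
  attr(rec, "dropped") <- c(length_mismatch = n_len_bad,
                            chromosome_overflow = n_overflow)
  rec
}

#' Assemble a balanced labelled dataset from positives and negatives
#'
#' Pairs positives with their negatives; when the background sampler
#' matched fewer than 100% of positives the unmatched positives are
#' dropped so the dataset stays 1:1 balanced.
#'
#' @param positives positive record data.frame
#' @param negatives negative record data.frame with a `paired_positive`
#'   column, or a `background_negatives` object
#' @return record data.frame (positives then negatives), attribute
#'   `n_dropped_positives`
#' @export
balanced_dataset <- function(positives, negatives) {
  if (inherits(negatives, "background_negatives"))
    negatives <- negatives$records
  keep <- positives$id %in% negatives$paired_positive
  pos <- positives[keep, , drop = FALSE]
  common <- intersect(names(pos), names(negatives))
  out <- rbind(pos[, common], negatives[negatives$paired_positive %in% pos$id,
                                        common, drop = FALSE])
  rownames(out) <- NULL
  attr(out, "n_dropped_positives") <- sum(!keep)
  out
}
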