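#' Interval and peak-set operations
#'
#' Throughout the package genomic intervals are data.frames with columns
#' `chrom`, `start`, `end` in the BED convention: 0-based, half-open.
#' @name intervals
NULL

.check_intervals <- function(x, what = "interval set") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop(what, " must have columns chrom, start, end")
  bad <- which(x$start >= x$end | x$start < 0)
  if (length(bad)) {
    ids <- if ("name" %in% names(x)) x$name[bad] else bad
    stop("malformed interval(s) (start >= end or start < 0): ",
         paste(head(ids, 5L), collapse = ", "))
  }
  invisible(x)
}

.sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

# IRanges view of 0-based half-open intervals (1-based closed internally)
.as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Merge overlapping or adjacent peaks
#'
#' Peaks that overlap by at least 1 bp or are directly adjacent are
#' combined into a single spanning interval, per chromosome.
#'
#' @param x data.frame of intervals (`chrom`, `start`, `end`)
#' @return sorted data.frame of disjoint, non-touching intervals covering
#'   every input base
#' @export
merge_peaks <- function(x) {
  .check_intervals(x)
  if (nrow(x) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  pieces <- lapply(split(x, x$chrom), function(d) {
    r <- IRanges::reduce(.as_iranges(d)) # default merges touching ranges
    data.frame(chrom = d$chrom[1L],
               start = IRanges::start(r) - 1L,
               end = IRanges::end(r))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  .sort_intervals(out)
}

#' Center an interval set and resize to fixed width
#'
#' Each interval is replaced by `width` bp around its center; odd-length
#' centers are floored to the lower coordinate. Intervals whose resized
#' form would leave the chromosome are dropped (and reported via the
#' `"dropped"` attribute).
#'
#' @param x data.frame of intervals
#' @param width target width in bp (default 300)
#' @param chrom_lengths named integer vector of chromosome lengths
#' @return data.frame of resized intervals, with attribute `dropped`
#'   holding the rows that did not fit
#' @export
center_and_resize <- function(x, width = 300L, chrom_lengths) {
  .check_intervals(x)
  center <- (x$start + x$end) %/% 2L # floor rule for odd lengths
  half <- width %/% 2L
  new_start <- center - half
  new_end <- new_start + width
  L <- chrom_lengths[as.character(x$chrom)]
  ok <- new_start >= 0L & new_end <= L
  out <- x
  out$start <- new_start
  out$end <- new_end
  dropped <- x[!ok, , drop = FALSE]
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(dropped))
    message(nrow(dropped), " interval(s) dropped: resized window exceeds chromosome")
  attr(out, "dropped") <- dropped
  out
}

#' Filter sequence records by chromosome pattern and alphabet
#'
#' Drops records on excluded chromosomes (alternative haplotypes,
#' unlocalized contigs by default) and records whose sequence contains
#' any character outside A,C,G,T (case-insensitive).
#'
#' @param records data.frame with at least `chrom` and `seq` columns
#' @param excluded_chrom_patterns character vector of regular expressions;
#'   records whose chromosome matches any pattern are dropped
#' @return surviving records, with attribute `drop_counts` (named counts
#'   per drop reason)
#' @export
filter_records <- function(records,
                           excluded_chrom_patterns = c("_alt$", "_random$", "^chrUn")) {
  chrom_bad <- rep(FALSE, nrow(records))
  for (p in excluded_chrom_patterns)
    chrom_bad <- chrom_bad | grepl(p, records$chrom)
  seq_bad <- grepl("[^ACGTacgt]", records$seq)
  keep <- !chrom_bad & !seq_bad
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_counts") <- c(
    excluded_chrom = sum(chrom_bad),
    `non-ACGT` = sum(seq_bad & !chrom_bad)
  )
  out
}

#' Pairwise overlap between two peak sets
#'
#' A pair (a, b) counts as overlapping when the intersection length is at
#' least `min_frac` of the shorter peak (`mode = "min"`) or of both peaks
#' (`mode = "reciprocal"`). The summary statistic is the number of
#' overlapping pairs divided by the number of peaks in the union of the
#' two sets, where the union count is `|A| + |B| - n_overlapping_pairs`.
#'
#' @param a,b data.frames of merged, sorted intervals
#' @param min_frac minimum overlap fraction (default 0.7)
#' @param mode `"min"` (one-sided, relative to the shorter peak) or
#'   `"reciprocal"`
#' @return list with `statistic`, `n_pairs`, logical flags `a_overlaps`
#'   and `b_overlaps`, and the pair table `pairs`
#' @export
peak_overlap <- function(a, b, min_frac = 0.7, mode = c("min", "reciprocal")) {
  mode <- match.arg(mode)
  .check_intervals(a, "set A"); .check_intervals(b, "set B")
  a_flag <- rep(FALSE, nrow(a)); b_flag <- rep(FALSE, nrow(b))
  pairs <- list()
  for (chrom in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chrom); ib <- which(b$chrom == chrom)
    ra <- .as_iranges(a[ia, ]); rb <- .as_iranges(b[ib, ])
    hits <- IRanges::findOverlaps(ra, rb)
    if (length(hits) == 0L) next
    qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
    inter <- pmin(a$end[ia][qa], b$end[ib][qb]) - pmax(a$start[ia][qa], b$start[ib][qb])
    wa <- a$end[ia][qa] - a$start[ia][qa]
    wb <- b$end[ib][qb] - b$start[ib][qb]
    qual <- if (mode == "min") inter >= min_frac * pmin(wa, wb)
            else inter >= min_frac * wa & inter >= min_frac * wb
    if (!any(qual)) next
    a_flag[ia[qa[qual]]] <- TRUE
    b_flag[ib[qb[qual]]] <- TRUE
    pairs[[chrom]] <- data.frame(chrom = chrom,
                                 a_index = ia[qa[qual]], b_index = ib[qb[qual]],
                                 intersection = inter[qual])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(chrom = character(), a_index = integer(), b_index = integer(),
               intersection = integer())
  rownames(pairs) <- NULL
  n_pairs <- nrow(pairs)
  denom <- nrow(a) + nrow(b) - n_pairs
  list(statistic = if (denom > 0) n_pairs / denom else NA_real_,
       n_pairs = n_pairs, a_overlaps = a_flag, b_overlaps = b_flag,
       pairs = pairs)
}

#' Read a narrowPeak (BED6+4) file
#' @param path file path
#' @return data.frame with narrowPeak columns; coordinates 0-based half-open
#' @export
read_narrowpeak <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "name", "score",
                                "strand", "signal", "pvalue", "qvalue", "summit"))
  .check_intervals(x, path)
  x
}

#' Write a narrowPeak (BED6+4) file
#'
#' Records are sorted, tab-separated and newline-terminated.
#' @param x data.frame; missing narrowPeak columns are filled with
#'   placeholders (score 0, strand ".", p/q -1, summit -1)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_narrowpeak <- function(x, path) {
  .check_intervals(x)
  n <- nrow(x)
  full <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else paste0("peak", seq_len(n)),
    score = if ("score" %in% names(x)) x$score else 0L,
    strand = if ("strand" %in% names(x)) x$strand else ".",
    signal = if ("signal" %in% names(x)) x$signal else 0,
    pvalue = if ("pvalue" %in% names(x)) x$pvalue else -1,
    qvalue = if ("qvalue" %in% names(x)) x$qvalue else -1,
    summit = if ("summit" %in% names(x)) x$summit else -1L
  )
  full <- .sort_intervals(full)
  write.table(full, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# total intersection of each interval in x with the (merged) interval set y,
# in bp; returns numeric vector along rows of x
interval_covered_by <- function(x, y) {
  out <- numeric(nrow(x))
  if (nrow(y) == 0L || nrow(x) == 0L) return(out)
  y <- merge_peaks(y)
  for (chrom in intersect(unique(x$chrom), unique(y$chrom))) {
    ix <- which(x$chrom == chrom); iy <- which(y$chrom == chrom)
    rx <- .as_iranges(x[ix, ]); ry <- .as_iranges(y[iy, ])
    hits <- IRanges::findOverlaps(rx, ry)
    if (length(hits) == 0L) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    inter <- pmin(x$end[ix][q], y$end[iy][s]) - pmax(x$start[ix][q], y$start[iy][s])
    agg <- tapply(inter, q, sum)
    out[ix[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}
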