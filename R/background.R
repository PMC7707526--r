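#' Matched genomic background sampling
#'
#' The second negative-set construction: windows drawn at random from the
#' genome, matched per positive for length (exactly), soft-masked repeat
#' base count (exactly, tolerance 0) and GC content (within `t_gc`, or
#' the same GC histogram bin in histogram mode), and excluded from any
#' overlap with the positive peaks, a user exclusion set, or previously
#' accepted negatives. Sampling proceeds in batches of candidate windows
#' for a bounded number of trials; a run that matches fewer than
#' `min_match_rate` of the positives fails with a per-GC-bin report of
#' the unmatched positives.
#' @name background
NULL

#' Configuration for matched background sampling
#'
#' @param t_gc GC-content tolerance (absolute difference; the study sweep
#'   used 0.02, 0.05 and 0.1)
#' @param t_repeat repeat tolerance; 0 means exactly equal soft-masked
#'   base counts (the only supported semantics for equal-length windows
#'   when 0; larger values allow that many bases of slack)
#' @param t_length length tolerance; 0 keeps candidate windows exactly as
#'   long as their positive
#' @param batchsize candidate windows drawn per trial (default 10000)
#' @param n_max_trials maximum number of batches (default 100)
#' @param min_match_rate minimum fraction of positives that must be
#'   matched, else the sampler fails with a report (default 0.80)
#' @param gc_mode `"tolerance"` (|dGC| <= t_gc) or `"histogram"`
#'   (negative falls in the positive's GC bin of width `bin_width`)
#' @param bin_width GC histogram bin width for histogram mode
#'   (default 0.02)
#' @param seed integer seed
#' @return a `background_config` list
#' @export
background_config <- function(t_gc = 0.02, t_repeat = 0L, t_length = 0L,
                              batchsize = 10000L, n_max_trials = 100L,
                              min_match_rate = 0.80,
                              gc_mode = c("tolerance", "histogram"),
                              bin_width = 0.02, seed = 1L) {
  gc_mode <- match.arg(gc_mode)
  stopifnot(t_gc >= 0, t_repeat >= 0, t_length >= 0,
            batchsize >= 1L, n_max_trials >= 1L,
            min_match_rate > 0, min_match_rate <= 1)
  structure(list(t_gc = t_gc, t_repeat = as.integer(t_repeat),
                 t_length = as.integer(t_length),
                 batchsize = as.integer(batchsize),
                 n_max_trials = as.integer(n_max_trials),
                 min_match_rate = min_match_rate, gc_mode = gc_mode,
                 bin_width = bin_width, seed = as.integer(seed)),
            class = "background_config")
}

.gc_bin <- function(gc, bin_width) as.integer(floor(gc / bin_width + 1e-9))

#' Sample GC/repeat/length-matched genomic background negatives
#'
#' Pairs each positive with one genome window satisfying the matching
#' contract (see [background_config()]). Matching is greedy first-fit in
#' input order; candidate windows are drawn uniformly over valid start
#' positions genome-wide, without replacement within a run.
#'
#' If fewer than `min_match_rate` of the positives can be matched after
#' `n_max_trials` batches, an error of class `negbench_match_failure` is
#' signalled; its `report` field lists unmatched positives by GC bin.
#' With a match rate in `[min_match_rate, 1)` the function returns
#' normally and the report records the unmatched positives, which callers
#' typically drop to keep datasets 1:1 balanced.
#'
#' @param genome a [bench_genome()]
#' @param positives data.frame of positive records (`id`, `chrom`,
#'   `start`, `end`, `seq`)
#' @param exclusions data.frame of intervals negatives must not touch;
#'   the positive peaks themselves are always excluded
#' @param config a [background_config()]
#' @return object of class `background_negatives`: list with `records`
#'   (negative records paired to positives), `report` (match rate,
#'   unmatched ids, per-GC-bin table, parameters) and `config`
#' @export
sample_matched_background <- function(genome, positives,
                                      exclusions = NULL,
                                      config = background_config()) {
  n_pos <- nrow(positives)
  if (n_pos == 0L) {
    return(structure(list(records = positives[0, ], report = list(
      match_rate = NA_real_, n_positives = 0L, unmatched = character(0),
      unmatched_by_gc_bin = table(integer(0)), trials_used = 0L),
      config = config), class = "background_negatives"))
  }
  pos_gc <- gc_fraction(positives$seq)
  pos_mask <- masked_count(positives$seq)
  pos_len <- nchar(positives$seq)
  pos_bin <- .gc_bin(pos_gc, config$bin_width)

  excl <- rbind(
    positives[, c("chrom", "start", "end")],
    if (!is.null(exclusions) && nrow(exclusions))
      exclusions[, c("chrom", "start", "end")]
  )
  excl <- merge_peaks(excl)
  excl_by_chrom <- split(excl, excl$chrom)

  chroms <- names(genome$seq)
  # draw windows of each distinct positive length, chromosome weighted by
  # the number of valid starts
  lens <- sort(unique(pos_len))
  matched_neg <- vector("list", n_pos)
  unmatched <- rep(TRUE, n_pos)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  acc_start <- lapply(chroms, function(x) numeric(0)) # accepted negatives
  acc_end <- lapply(chroms, function(x) numeric(0))
  names(acc_start) <- names(acc_end) <- chroms
  trials_used <- 0L

  with_seed(config$seed, {
    for (trial in seq_len(config$n_max_trials)) {
      if (!any(unmatched)) break
      trials_used <- trial
      for (w in lens) {
        if (!any(unmatched[pos_len == w])) next
        valid <- pmax(genome$lengths - w + 1L, 0L)
        if (sum(valid) == 0L) stop("genome exhausted: no window of length ", w)
        ci <- sample.int(length(chroms), config$batchsize, replace = TRUE,
                         prob = valid / sum(valid))
        st <- floor(runif(config$batchsize) * valid[ci])
        cand_chrom <- chroms[ci]
        cand_start <- as.integer(st)
        cand_end <- cand_start + as.integer(w)

        # drop repeats of windows already tried in this run
        key <- paste0(cand_chrom, ":", cand_start, "-", w)
        fresh <- !vapply(key, function(k2) !is.null(seen[[k2]]), logical(1),
                         USE.NAMES = FALSE)
        for (k2 in key[fresh]) seen[[k2]] <- TRUE
        if (!any(fresh)) next
        cand_chrom <- cand_chrom[fresh]; cand_start <- cand_start[fresh]
        cand_end <- cand_end[fresh]

        # composition and exclusion screening per chromosome
        keep <- logical(length(cand_chrom))
        gc <- numeric(length(cand_chrom)); mk <- integer(length(cand_chrom))
        for (chrom in unique(cand_chrom)) {
          idx <- which(cand_chrom == chrom)
          comp <- window_composition(genome, chrom, cand_start[idx], cand_end[idx])
          gc[idx] <- comp$gc
          mk[idx] <- comp$mask_count
          ex <- excl_by_chrom[[chrom]]
          if (!is.null(ex) && nrow(ex)) {
            hits <- IRanges::findOverlaps(
              IRanges::IRanges(cand_start[idx] + 1L, cand_end[idx]),
              IRanges::IRanges(ex$start + 1L, ex$end))
            bad <- unique(S4Vectors::queryHits(hits))
            keep[idx] <- !seq_along(idx) %in% bad
          } else keep[idx] <- TRUE
        }
        ord <- which(keep)
        if (!length(ord)) next

        for (i in ord) {
          un <- which(unmatched & pos_len == w)
          if (!length(un)) break
          # no overlap with already-accepted negatives
          as_ <- acc_start[[cand_chrom[i]]]; ae_ <- acc_end[[cand_chrom[i]]]
          if (length(as_) && any(cand_start[i] < ae_ & cand_end[i] > as_)) next
          ok <- abs(mk[i] - pos_mask[un]) <= config$t_repeat
          if (config$gc_mode == "tolerance") {
            ok <- ok & abs(gc[i] - pos_gc[un]) <= config$t_gc + 1e-12
          } else {
            ok <- ok & .gc_bin(gc[i], config$bin_width) == pos_bin[un]
          }
          if (!any(ok)) next
          j <- un[which(ok)[1L]] # greedy first-fit in input order
          matched_neg[[j]] <- data.frame(
            id = paste0(positives$id[j], "_bg"),
            chrom = cand_chrom[i], start = cand_start[i], end = cand_end[i],
            strand = "+",
            seq = extract_sequence(genome, cand_chrom[i], cand_start[i], cand_end[i]),
            label = 0L,
            cell_line = if ("cell_line" %in% names(positives))
              positives$cell_line[j] else NA,
            neg_type = paste0("background_", config$gc_mode),
            paired_positive = positives$id[j],
            stringsAsFactors = FALSE)
          unmatched[j] <- FALSE
          acc_start[[cand_chrom[i]]] <- c(as_, cand_start[i])
          acc_end[[cand_chrom[i]]] <- c(ae_, cand_end[i])
        }
      }
      if (!any(unmatched)) break
    }
  })

  match_rate <- mean(!unmatched)
  bin_tab <- table(bin_low = sprintf("%.2f", pos_bin[unmatched] * config$bin_width))
  report <- list(match_rate = match_rate, n_positives = n_pos,
                 n_matched = sum(!unmatched),
                 unmatched = positives$id[unmatched],
                 unmatched_by_gc_bin = bin_tab,
                 trials_used = trials_used,
                 parameters = unclass(config))
  if (match_rate < config$min_match_rate) {
    cond <- structure(class = c("negbench_match_failure", "error", "condition"),
                      list(message = sprintf(
                        "background matching failed: %.1f%% matched (< %.0f%% required); %d unmatched positives (see $report)",
                        100 * match_rate, 100 * config$min_match_rate,
                        sum(unmatched)),
                        call = sys.call(-1), report = report))
    stop(cond)
  }
  records <- do.call(rbind, matched_neg[!unmatched])
  rownames(records) <- NULL
  structure(list(records = records, report = report, config = config),
            class = "background_negatives")
}

#' @export
print.background_negatives <- function(x, ...) {
  cat(sprintf("<background_negatives> %d/%d positives matched (%.1f%%), mode %s, t_gc %.3g\n",
              x$report$n_matched, x$report$n_positives,
              100 * x$report$match_rate, x$config$gc_mode, x$config$t_gc))
  invisible(x)
}

#' Sample background negatives matching the positive GC histogram
#'
#' Convenience wrapper around [sample_matched_background()] with
#' `gc_mode = "histogram"`: each negative must fall in its positive's GC
#' bin, so per-bin counts of negatives equal per-bin counts of positives
#' exactly wherever the genome supplies enough windows; shortfalls are
#' reported per bin, never silently substituted from other bins.
#'
#' @inheritParams sample_matched_background
#' @param bin_width GC bin width (default 0.02)
#' @return a `background_negatives` object
#' @export
sample_histogram_matched <- function(genome, positives, exclusions = NULL,
                                     bin_width = 0.02,
                                     config = background_config()) {
  config$gc_mode <- "histogram"
  config$bin_width <- bin_width
  sample_matched_background(genome, positives, exclusions, config)
}
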