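#' Genome container with soft-mask-aware sequence access
#'
#' A lightweight in-memory genome: named chromosome sequences (character
#' strings, lowercase = soft-masked repeat) plus per-chromosome cumulative
#' GC and mask counts so any window's composition is an O(1) lookup.
#'
#' @param seqs named character vector of chromosome sequences
#' @param islands optional data.frame of GC-rich island truth intervals
#'   (chrom, start, end; 0-based half-open)
#' @param repeats optional data.frame of soft-masked repeat intervals
#' @param spec optional [genome_spec()] the genome was generated from
#' @return an object of class `bench_genome`
#' @export
bench_genome <- function(seqs, islands = NULL, repeats = NULL, spec = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  g <- list(
    seq = seqs,
    lengths = setNames(nchar(seqs), names(seqs)),
    islands = islands,
    repeats = repeats,
    spec = spec,
    cache = new.env(parent = emptyenv())
  )
  class(g) <- "bench_genome"
  g
}

#' @export
print.bench_genome <- function(x, ...) {
  cat("<bench_genome> ", length(x$seq), " chromosome(s), ",
      format(sum(as.numeric(x$lengths)), big.mark = ","), " bp total\n", sep = "")
  for (nm in names(x$seq)) {
    cat("  ", nm, ": ", format(x$lengths[[nm]], big.mark = ","), " bp\n", sep = "")
  }
  invisible(x)
}

# cumulative (G|C) and lowercase counts; index i+1 = count over first i bases
.genome_cum <- function(genome, chrom) {
  key <- paste0("cum_", chrom)
  if (!is.null(genome$cache[[key]])) return(genome$cache[[key]])
  v <- utf8ToInt(genome$seq[[chrom]])
  gc <- (v == 71L | v == 103L | v == 67L | v == 99L)
  mask <- (v >= 97L & v <= 122L)
  res <- list(gc = c(0, cumsum(as.integer(gc))),
              mask = c(0, cumsum(as.integer(mask))))
  genome$cache[[key]] <- res
  res
}

#' Window composition from a genome
#'
#' GC and soft-masked base counts for 0-based half-open windows, computed
#' from cumulative tables (O(1) per window).
#' @param genome a [bench_genome()]
#' @param chrom chromosome name (scalar)
#' @param start,end integer vectors of 0-based half-open coordinates
#' @return data.frame with columns `gc_count`, `mask_count`, `width`, `gc`
#' @export
window_composition <- function(genome, chrom, start, end) {
  cum <- .genome_cum(genome, chrom)
  gc_count <- cum$gc[end + 1L] - cum$gc[start + 1L]
  mask_count <- cum$mask[end + 1L] - cum$mask[start + 1L]
  w <- end - start
  data.frame(gc_count = gc_count, mask_count = mask_count, width = w,
             gc = gc_count / w)
}

#' Extract the sequence of a genomic interval
#'
#' Case (soft-masking) is preserved; minus-strand intervals are
#' reverse-complemented with case travelling with each base.
#'
#' @param genome a [bench_genome()]
#' @param chrom chromosome name
#' @param start,end 0-based half-open coordinates
#' @param strand `"+"`, `"-"` or `"."`
#' @return a character string of length `end - start`
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome$seq))
    stop("unknown chromosome: ", chrom)
  L <- genome$lengths[[chrom]]
  if (any(start < 0L) || any(end > L) || any(start >= end))
    stop(sprintf("interval out of bounds: %s:%d-%d (chromosome length %d)",
                 chrom, start, end, L))
  s <- substring(genome$seq[[chrom]], start + 1L, end)
  if (identical(strand, "-")) s <- rev_comp(s)
  s
}

#' Extract sequences for a set of intervals
#'
#' Vectorised companion to [extract_sequence()]; intervals may span
#' several chromosomes and carry a `strand` column.
#' @param genome a [bench_genome()]
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `strand`
#' @return character vector of sequences, one per row
#' @export
extract_sequences <- function(genome, intervals) {
  n <- nrow(intervals)
  out <- character(n)
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep("+", n)
  for (chrom in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == chrom)
    L <- genome$lengths[[chrom]]
    if (is.null(L)) stop("unknown chromosome: ", chrom)
    st <- intervals$start[idx]; en <- intervals$end[idx]
    if (any(st < 0L) || any(en > L) || any(st >= en))
      stop("interval out of bounds on ", chrom)
    s <- substring(genome$seq[[chrom]], st + 1L, en)
    flip <- strand[idx] == "-"
    if (any(flip)) s[flip] <- rev_comp(s[flip])
    out[idx] <- s
  }
  out
}

#' Write a genome to a soft-masked FASTA file
#'
#' 60-column wrapped; lowercase soft-masking is preserved.
#' @param genome a [bench_genome()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::BStringSet(genome$seq)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a soft-masked FASTA file into a genome object
#' @param path FASTA file path
#' @return a [bench_genome()]
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  bench_genome(seqs)
}

# replace substring [start, end) of chromosome (0-based half-open)
.genome_splice <- function(seqs, chrom, start, replacement) {
  s <- seqs[[chrom]]
  substr(s, start + 1L, start + nchar(replacement)) <- replacement
  seqs[[chrom]] <- s
  seqs
}
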