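#' @useDynLib negbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rpois sd cor quantile setNames ecdf
#' @importFrom utils head combn write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# byte -> base code lookup (A/a=1, C/c=2, G/g=3, T/t=4, else NA)
.base_code_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut
})

#' Encode a DNA string as integer base codes
#'
#' A/a -> 1, C/c -> 2, G/g -> 3, T/t -> 4; anything else -> NA.
#' @param x a single character string
#' @return integer vector of length `nchar(x)`
#' @keywords internal
seq_codes <- function(x) {
  .base_code_lut[utf8ToInt(x)]
}

#' Reverse complement preserving letter case
#'
#' Soft-masking (lowercase) travels with the base it annotates, so the
#' reverse complement of `"gtAC"` is `"GTac"`.
#' @param x character vector of DNA strings
#' @return character vector of the same length
#' @export
rev_comp <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' GC fraction of sequences
#'
#' Case-insensitive count of G and C over the sequence length.
#' @param x character vector of DNA strings
#' @return numeric vector in \[0, 1\]
#' @export
gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- vapply(x, function(s) {
    v <- utf8ToInt(s)
    sum(v == 71L | v == 103L | v == 67L | v == 99L)
  }, integer(1), USE.NAMES = FALSE)
  ifelse(n > 0L, gc / n, NA_real_)
}

#' Count soft-masked (lowercase) bases
#' @param x character vector of DNA strings
#' @return integer vector
#' @export
masked_count <- function(x) {
  vapply(x, function(s) {
    v <- utf8ToInt(s)
    sum(v >= 97L & v <= 122L)
  }, integer(1), USE.NAMES = FALSE)
}

# Deterministic 32-bit hash of a string, for per-record RNG streams.
.string_hash <- function(x) {
  v <- utf8ToInt(x)
  h <- 5381
  for (b in v) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

#' Derive a per-record seed from a global seed and a record identifier
#'
#' Per-record streams make results independent of processing order.
#' @param seed integer global seed
#' @param id character record identifier
#' @return integer seed below 2^31
#' @export
derive_seed <- function(seed, id) {
  as.integer((as.numeric(seed) %% 2147483647 * 31 + .string_hash(as.character(id))) %%
               2147483647)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so surrounding code is unaffected.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the two empirical CDFs. Computed
#' directly (no p-value) so tied values need no special handling.
#' @param x,y numeric vectors
#' @return the KS statistic, a number in \[0, 1\]
#' @export
ks_statistic <- function(x, y) {
  x <- sort(x); y <- sort(y)
  z <- sort(unique(c(x, y)))
  fx <- findInterval(z, x) / length(x)
  fy <- findInterval(z, y) / length(y)
  max(abs(fx - fy))
}
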