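#' Motif models (position probability matrices)
#'
#' A motif is a list with a `name` and a `matrix`: width x 4 probability
#' matrix with columns A, C, G, T, each row summing to 1. A motif library
#' is a named list of motifs with class `motif_library`.
#' @name motifs
NULL

#' Construct a motif model
#' @param name motif name
#' @param matrix width x 4 probability matrix (columns A, C, G, T)
#' @return a `motif_model`
#' @export
motif_model <- function(name, matrix) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("motif matrix must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 4L) stop("motif width must be >= 4")
  if (any(abs(rowSums(matrix) - 1) > 1e-9))
    stop("motif matrix rows must sum to 1")
  colnames(matrix) <- DNA_BASES
  structure(list(name = name, matrix = matrix), class = "motif_model")
}

#' Information content of a motif (bits)
#'
#' Sum over columns of 2 - H(column), H in bits; uniform background.
#' @param motif a `motif_model`
#' @return total information content in bits
#' @export
motif_ic <- function(motif) {
  p <- motif$matrix
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  sum(2 - h)
}

#' Consensus sequence of a motif
#' @param motif a `motif_model`
#' @return character string, most probable base per column
#' @export
motif_consensus <- function(motif) {
  paste0(DNA_BASES[apply(motif$matrix, 1L, which.max)], collapse = "")
}

#' Generate a synthetic motif library
#'
#' Random high-information position probability matrices: one dominant
#' base per column (probability `dominance`), remainder spread equally.
#' Widths are drawn from `widths`; with the default dominance of 0.85 an
#' 8-wide motif carries about 9 bits, comfortably above typical scan
#' thresholds.
#'
#' @param n number of motifs (default 8)
#' @param widths integer vector of candidate widths (default 8:12)
#' @param dominance probability of the consensus base per column
#' @param min_ic minimum total information content in bits (resampled
#'   until met; default 8)
#' @param seed integer seed
#' @return a `motif_library` (named list of `motif_model`s)
#' @export
random_motif_library <- function(n = 8L, widths = 8:12, dominance = 0.9,
                                 min_ic = 8, seed = 1L) {
  with_seed(seed, {
    lib <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        w <- sample(widths, 1L)
        cons <- sample.int(4L, w, replace = TRUE)
        m <- matrix((1 - dominance) / 3, nrow = w, ncol = 4L)
        m[cbind(seq_len(w), cons)] <- dominance
        mot <- motif_model(sprintf("M%02d", i), m)
        if (motif_ic(mot) >= min_ic) break
      }
      lib[[i]] <- mot
    }
    names(lib) <- vapply(lib, `[[`, "", "name")
    structure(lib, class = "motif_library")
  })
}

#' @export
print.motif_library <- function(x, ...) {
  cat("<motif_library> ", length(x), " motifs\n", sep = "")
  for (m in x)
    cat(sprintf("  %s  width %d  IC %.1f bits  consensus %s\n",
                m$name, nrow(m$matrix), motif_ic(m), motif_consensus(m)))
  invisible(x)
}

#' Sample a sequence realisation from a motif
#'
#' Each position is drawn independently from its probability row
#' (categorical per column). When a `scan_threshold` (as produced for
#' [scan_motifs()]) is supplied, draws are rejected until the instance's
#' own log-odds score reaches the threshold — planted sites are then
#' bona fide detectable binding sites — falling back to the consensus
#' after `max_tries`. Uses the current RNG stream.
#' @param motif a `motif_model`
#' @param scan_threshold optional list with `wi` (integer log-odds
#'   matrix) and `threshold`, see `motif_scan_config()`
#' @param max_tries rejection-sampling cap (default 50)
#' @return character string of the motif's width
#' @export
sample_motif_instance <- function(motif, scan_threshold = NULL,
                                  max_tries = 50L) {
  p <- motif$matrix
  for (t in seq_len(max_tries)) {
    idx <- apply(p, 1L, function(row) sample.int(4L, 1L, prob = row))
    if (is.null(scan_threshold)) break
    sc <- sum(scan_threshold$wi[cbind(seq_len(nrow(p)), idx)])
    if (sc >= scan_threshold$threshold) break
    idx <- NULL
  }
  if (is.null(idx)) idx <- apply(p, 1L, which.max) # consensus fallback
  paste0(DNA_BASES[idx], collapse = "")
}

#' Write a motif library as JASPAR-style PFM text
#'
#' One block per motif: a `>name` header then four rows
#' `A [ ... ]` ... `T [ ... ]` of per-position probabilities.
#' @param library a `motif_library`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_motif_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in library) {
    writeLines(paste0(">", m$name), con)
    for (j in 1:4) {
      writeLines(paste0(DNA_BASES[j], " [ ",
                        paste(formatC(m$matrix[, j], digits = 6, format = "f"),
                              collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Read a JASPAR-style PFM text file
#'
#' Accepts probability or count matrices (counts are normalised per
#' column of the motif, i.e. per sequence position).
#' @param path input path
#' @return a `motif_library`
#' @export
read_motif_library <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif headers ('>') found in ", path)
  lib <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    name <- sub("^>\\s*", "", lines[from])
    name <- sub("\\s.*$", "", name)
    rows <- lines[(from + 1L):to]
    if (length(rows) < 4L) stop("motif ", name, ": expected 4 base rows")
    vals <- lapply(rows[1:4], function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("[\\[\\]]", " ", r, perl = TRUE)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    m <- do.call(cbind, vals) # width x 4
    m <- m / rowSums(m)
    lib[[name]] <- motif_model(name, m)
  }
  structure(lib, class = "motif_library")
}
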