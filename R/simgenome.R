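#' Synthetic genome specification
#'
#' Defines a multi-chromosome soft-masked genome with heterogeneous GC.
#' Background sequence is an order-`markov_order` Markov chain with
#' randomly perturbed transition preferences (giving the genome skewed,
#' genuinely non-uniform word usage) and CpG depletion (the `C -> G`
#' transition damped by `cpg_depletion`), calibrated so the stationary
#' GC hits `background_gc`.
#' GC-rich islands emulate CpG-island/promoter-like territory and make
#' the open-chromatin GC distribution bimodal when elements are allowed
#' inside them. Repeats are soft-masked blocks copied (with 10%
#' substitution) from a small set of family consensus sequences, so
#' repeated k-mers are genuinely frequent genome-wide.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp,
#'   each >= 1000)
#' @param background_gc stationary GC of non-island background, in (0,1)
#' @param gc_rich_island_rate expected islands per Mb (Poisson)
#' @param island_gc stationary GC inside islands
#' @param island_length island width in bp
#' @param repeat_fraction target soft-masked fraction, in \[0,1\]
#' @param repeat_block_length length of one repeat block (bp)
#' @param n_repeat_families number of repeat consensus sequences
#' @param cpg_depletion multiplier on the C->G transition (1 = none)
#' @param markov_order order of the background Markov chain (default 2)
#' @param chain_concentration Gamma concentration of the random
#'   per-transition perturbations; smaller values give the genome
#'   stronger higher-order structure (more skewed word usage, as in real
#'   genomes). 1e6 or more is effectively unperturbed.
#' @param seed integer seed; generation is a pure function of (spec, seed)
#' @return a `genome_spec` list
#' @export
genome_spec <- function(chrom_lengths = c(chr1 = 1500000L, chr2 = 1500000L,
                                          chr8 = 1000000L, chr21 = 800000L),
                        background_gc = 0.41,
                        gc_rich_island_rate = 12,
                        island_gc = 0.62,
                        island_length = 2000L,
                        repeat_fraction = 0.10,
                        repeat_block_length = 500L,
                        n_repeat_families = 3L,
                        cpg_depletion = 0.25,
                        markov_order = 2L,
                        chain_concentration = 5,
                        seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1L, !is.null(names(chrom_lengths)))
  if (any(chrom_lengths < 1000L)) stop("chromosome lengths must be >= 1000 bp")
  for (f in c(background_gc, island_gc, repeat_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (repeat_fraction > 0 && any(chrom_lengths < repeat_block_length))
    stop("chromosome shorter than one repeat block")
  structure(list(chrom_lengths = chrom_lengths, background_gc = background_gc,
                 gc_rich_island_rate = gc_rich_island_rate,
                 island_gc = island_gc, island_length = as.integer(island_length),
                 repeat_fraction = repeat_fraction,
                 repeat_block_length = as.integer(repeat_block_length),
                 n_repeat_families = as.integer(n_repeat_families),
                 cpg_depletion = cpg_depletion,
                 markov_order = as.integer(markov_order),
                 chain_concentration = chain_concentration,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# order-o chain with CpG depletion and per-transition perturbations W
# (4^o x 4, positive), calibrated so the stationary GC equals `gc`.
# W != 1 gives the genome genuine higher-order structure: common and rare
# words, as in real genomes, which k-mer shuffling destroys.
.chain_params <- function(gc, cpg_depletion, W = NULL, order = 1L) {
  S <- 4L^order
  if (is.null(W)) W <- matrix(1, S, 4L)
  stopifnot(nrow(W) == S, ncol(W) == 4L)
  ends_in_C <- (seq_len(S) - 1L) %% 4L == 1L
  make_trans <- function(u) {
    q <- c((1 - u) / 2, u / 2, u / 2, (1 - u) / 2)
    tr <- W * matrix(q, S, 4L, byrow = TRUE)
    tr[ends_in_C, 3L] <- tr[ends_in_C, 3L] * cpg_depletion
    tr / rowSums(tr)
  }
  stationary <- function(tr) {
    p <- rep(1 / S, S)
    rest <- seq_len(S %/% 4L)
    for (it in 1:500) {
      pn <- numeric(S)
      for (b in 1:4) {
        v <- rowSums(matrix(p * tr[, b], nrow = S %/% 4L))
        pn[4L * (rest - 1L) + b] <- v
      }
      if (max(abs(pn - p)) < 1e-13) { p <- pn; break }
      p <- pn
    }
    p
  }
  if (gc <= 0 || gc >= 1) {
    q <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    tr <- matrix(q, S, 4L, byrow = TRUE)
    return(list(trans = tr, init = rep(1 / S, S), order = order))
  }
  last_gc <- (seq_len(S) - 1L) %% 4L %in% c(1L, 2L)
  u <- stats::uniroot(function(u) {
    sum(stationary(make_trans(u))[last_gc]) - gc
  }, c(1e-4, 1 - 1e-4), tol = 1e-9)$root
  tr <- make_trans(u)
  list(trans = tr, init = stationary(tr), order = order)
}

# greedily place n non-overlapping [start, start+w) blocks on [0, L)
# avoiding `occupied` (2-column matrix start,end); returns starts
.place_blocks <- function(L, n, w, occupied = NULL, max_tries = 200L) {
  starts <- integer(0)
  occ_s <- if (is.null(occupied)) numeric(0) else occupied[, 1]
  occ_e <- if (is.null(occupied)) numeric(0) else occupied[, 2]
  tries <- 0L
  while (length(starts) < n && tries < max_tries * n) {
    tries <- tries + 1L
    st <- as.integer(floor(runif(1) * (L - w + 1L)))
    if (length(occ_s) && any(st < occ_e & st + w > occ_s)) next
    starts <- c(starts, st)
    occ_s <- c(occ_s, st); occ_e <- c(occ_e, st + w)
  }
  starts
}

#' Generate a synthetic soft-masked genome
#'
#' Deterministic given the spec (which carries the seed): background
#' Markov sequence per chromosome, GC-rich islands spliced in, repeat
#' blocks copied from family consensus sequences, mutated and
#' soft-masked (lowercased). Truth tables for islands and repeats are
#' attached to the returned genome.
#'
#' @param spec a [genome_spec()]
#' @return a [bench_genome()] with `islands` and `repeats` truth tables
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    S <- 4L^spec$markov_order
    W <- matrix(pmax(rgamma(S * 4L, shape = spec$chain_concentration,
                            rate = spec$chain_concentration), 1e-3), S, 4L)
    bg <- .chain_params(spec$background_gc, spec$cpg_depletion, W,
                        spec$markov_order)
    isl <- .chain_params(spec$island_gc, spec$cpg_depletion, W,
                         spec$markov_order)
    seqs <- character(0)
    island_rows <- list()
    repeat_rows <- list()
    # repeat family consensus sequences (background composition)
    fams <- character(spec$n_repeat_families)
    if (spec$repeat_fraction > 0) {
      for (i in seq_len(spec$n_repeat_families))
        fams[i] <- cpp_markov_seq(spec$repeat_block_length, bg$trans, bg$init, bg$order)
    }
    for (chrom in names(spec$chrom_lengths)) {
      L <- spec$chrom_lengths[[chrom]]
      # work on a character vector; paste once at the end
      ch <- strsplit(cpp_markov_seq(L, bg$trans, bg$init, bg$order), "")[[1]]
      occupied <- NULL
      # GC-rich islands
      n_isl <- rpois(1L, spec$gc_rich_island_rate * L / 1e6)
      n_isl <- min(n_isl, L %/% (2L * spec$island_length))
      if (n_isl > 0L) {
        st <- .place_blocks(L, n_isl, spec$island_length)
        for (p in st) {
          piece <- cpp_markov_seq(spec$island_length, isl$trans, isl$init, isl$order)
          ch[(p + 1L):(p + spec$island_length)] <- strsplit(piece, "")[[1]]
        }
        if (length(st)) {
          island_rows[[chrom]] <- data.frame(chrom = chrom, start = st,
                                             end = st + spec$island_length)
          occupied <- cbind(st, st + spec$island_length)
        }
      }
      # soft-masked repeat blocks
      if (spec$repeat_fraction > 0) {
        n_rep <- round(L * spec$repeat_fraction / spec$repeat_block_length)
        if (n_rep > 0L) {
          st <- .place_blocks(L, n_rep, spec$repeat_block_length, occupied)
          if (length(st)) {
            fam_idx <- sample.int(spec$n_repeat_families, length(st),
                                  replace = TRUE)
            for (i in seq_along(st)) {
              block <- strsplit(fams[fam_idx[i]], "")[[1]]
              # ~10% substitutions, then lowercase = soft mask
              nmut <- rbinom(1L, spec$repeat_block_length, 0.1)
              if (nmut > 0L) {
                pos <- sample.int(spec$repeat_block_length, nmut)
                block[pos] <- sample(DNA_BASES, nmut, replace = TRUE)
              }
              ch[(st[i] + 1L):(st[i] + spec$repeat_block_length)] <-
                tolower(block)
            }
            repeat_rows[[chrom]] <- data.frame(
              chrom = chrom, start = st, end = st + spec$repeat_block_length,
              family = fam_idx)
          }
        }
      }
      seqs[[chrom]] <- paste(ch, collapse = "")
    }
    islands <- if (length(island_rows)) .sort_intervals(do.call(rbind, island_rows))
               else data.frame(chrom = character(), start = integer(), end = integer())
    repeats <- if (length(repeat_rows)) .sort_intervals(do.call(rbind, repeat_rows))
               else data.frame(chrom = character(), start = integer(),
                               end = integer(), family = integer())
    rownames(islands) <- rownames(repeats) <- NULL
    bench_genome(seqs, islands = islands, repeats = repeats, spec = spec)
  })
}

#' Cell-line model for element planting
#'
#' @param name cell line name
#' @param active_motifs character vector of motif names active in this
#'   line (non-empty subset of the library)
#' @param peak_count number of open-chromatin elements (>= 1)
#' @param motifs_per_element integer range (min, max) of planted motif
#'   instances per element
#' @param element_width element width in bp (default 300)
#' @return a `cell_line_model`
#' @export
cell_line_model <- function(name, active_motifs, peak_count,
                            motifs_per_element = c(2L, 6L),
                            element_width = 300L) {
  stopifnot(length(active_motifs) >= 1L, peak_count >= 1L,
            length(motifs_per_element) == 2L,
            motifs_per_element[1] >= 1L,
            motifs_per_element[2] >= motifs_per_element[1])
  structure(list(name = name, active_motifs = active_motifs,
                 peak_count = as.integer(peak_count),
                 motifs_per_element = as.integer(motifs_per_element),
                 element_width = as.integer(element_width)),
            class = "cell_line_model")
}

#' Plant motif-defined regulatory elements into a genome
#'
#' Places non-overlapping elements outside repeat blocks — a configurable
#' fraction inside GC-rich islands — and writes sampled motif instances
#' (random strand, sequence drawn from the PWM columns) into the genome
#' sequence. A shared pool of elements is open in every cell line; the
#' remainder are exclusive to one line, which keeps the
#' tissue-specificity task non-degenerate.
#'
#' @param genome a [bench_genome()] from [generate_genome()]
#' @param motif_library a `motif_library`
#' @param cell_lines list of [cell_line_model()]s
#' @param shared_fraction fraction of each line's peaks drawn from the
#'   shared pool (default 0.3)
#' @param island_element_fraction fraction of elements placed inside
#'   GC-rich islands (default 0.15)
#' @param scan_config a [motif_scan_config()]; planted instances are
#'   rejection-sampled to score above this scan threshold, so a scan of
#'   the emitted positives at the same threshold recovers them
#' @param seed integer seed
#' @return list with `genome` (sequence updated with planted instances),
#'   `peaks` (named list of narrowPeak-style data.frames per line,
#'   signal = planted motif count), `elements` (element truth table) and
#'   `truth` (per-instance truth table: chrom, start, end, strand, motif,
#'   element id, line)
#' @export
plant_elements <- function(genome, motif_library, cell_lines,
                           shared_fraction = 0.3,
                           island_element_fraction = 0.15,
                           scan_config = motif_scan_config(),
                           seed = 1L) {
  stopifnot(inherits(genome, "bench_genome"))
  scan_thresholds <- lapply(motif_library, .pwm_threshold, config = scan_config)
  line_names <- vapply(cell_lines, `[[`, "", "name")
  names(cell_lines) <- line_names
  for (cl in cell_lines)
    if (!all(cl$active_motifs %in% names(motif_library)))
      stop("unknown motif in active set of line ", cl$name)
  width <- unique(vapply(cell_lines, `[[`, integer(1), "element_width"))
  if (length(width) != 1L) stop("all lines must share one element width")

  peak_counts <- vapply(cell_lines, `[[`, integer(1), "peak_count")
  n_shared <- as.integer(round(shared_fraction * min(peak_counts)))
  n_excl <- peak_counts - n_shared
  n_total <- n_shared + sum(n_excl)

  chroms <- names(genome$seq)
  lens <- genome$lengths
  isl <- genome$islands
  rep_ <- genome$repeats

  with_seed(seed, {
    # ---- choose element positions -------------------------------------
    n_island_elems <- as.integer(round(island_element_fraction * n_total))
    pos_chrom <- character(0); pos_start <- integer(0); pos_island <- logical(0)
    occ <- lapply(chroms, function(x)
      if (!is.null(rep_) && nrow(rep_)) {
        r <- rep_[rep_$chrom == x, ]
        cbind(r$start, r$end)
      } else cbind(numeric(0), numeric(0)))
    names(occ) <- chroms
    add_occ <- function(chrom, st) occ[[chrom]] <<- rbind(occ[[chrom]], c(st, st + width))

    # island elements: inside a random island, clear of repeats/others
    if (n_island_elems > 0L) {
      if (is.null(isl) || nrow(isl) == 0L)
        stop("island elements requested but the genome has no GC-rich islands")
      tries <- 0L
      while (sum(pos_island) < n_island_elems && tries < 500L * n_island_elems) {
        tries <- tries + 1L
        i <- sample.int(nrow(isl), 1L)
        room <- isl$end[i] - isl$start[i] - width
        if (room < 0L) next
        st <- isl$start[i] + as.integer(floor(runif(1) * (room + 1L)))
        o <- occ[[isl$chrom[i]]]
        if (nrow(o) && any(st < o[, 2] & st + width > o[, 1])) next
        pos_chrom <- c(pos_chrom, isl$chrom[i]); pos_start <- c(pos_start, st)
        pos_island <- c(pos_island, TRUE)
        add_occ(isl$chrom[i], st)
      }
      if (sum(pos_island) < n_island_elems)
        stop("could not place ", n_island_elems, " island elements (placed ",
             sum(pos_island), "): genome islands too small or crowded")
    }
    # background elements: outside repeats and islands
    n_bg_elems <- n_total - n_island_elems
    occ_isl <- lapply(chroms, function(x)
      if (!is.null(isl) && nrow(isl)) {
        r <- isl[isl$chrom == x, ]
        cbind(r$start, r$end)
      } else cbind(numeric(0), numeric(0)))
    names(occ_isl) <- chroms
    placed <- 0L; tries <- 0L
    valid <- pmax(lens - width + 1L, 0L)
    while (placed < n_bg_elems && tries < 500L * n_bg_elems) {
      tries <- tries + 1L
      ci <- sample.int(length(chroms), 1L, prob = valid / sum(valid))
      chrom <- chroms[ci]
      st <- as.integer(floor(runif(1) * valid[ci]))
      o <- rbind(occ[[chrom]], occ_isl[[chrom]])
      if (nrow(o) && any(st < o[, 2] & st + width > o[, 1])) next
      pos_chrom <- c(pos_chrom, chrom); pos_start <- c(pos_start, st)
      pos_island <- c(pos_island, FALSE)
      add_occ(chrom, st)
      placed <- placed + 1L
    }
    if (placed < n_bg_elems)
      stop("could not place ", n_bg_elems, " elements outside repeats/islands ",
           "(placed ", placed, "): genome too small for the requested peak counts")

    # shuffle element order so shared/island/exclusive status is independent
    # of placement order
    ord <- sample.int(n_total)
    pos_chrom <- pos_chrom[ord]; pos_start <- pos_start[ord]
    pos_island <- pos_island[ord]
    elements <- data.frame(
      element_id = sprintf("el%05d", seq_len(n_total)),
      chrom = pos_chrom, start = pos_start, end = pos_start + width,
      island = pos_island, stringsAsFactors = FALSE)

    # assign: first n_shared shared, then exclusive slices per line
    assign_lines <- vector("list", n_total)
    for (i in seq_len(n_shared)) assign_lines[[i]] <- line_names
    at <- n_shared
    for (ln in line_names) {
      k <- n_excl[[ln]]
      if (k > 0L) for (i in seq_len(k)) assign_lines[[at + i]] <- ln
      at <- at + k
    }
    elements$lines <- vapply(assign_lines, paste, "", collapse = ",")

    # ---- plant motif instances ----------------------------------------
    # character-vector views of chromosomes that receive instances
    seq_chars <- new.env(parent = emptyenv())
    truth <- list()
    signal <- setNames(integer(n_total), elements$element_id)
    for (i in seq_len(n_total)) {
      el_occ_s <- integer(0); el_occ_e <- integer(0)
      for (ln in assign_lines[[i]]) {
        cl <- cell_lines[[ln]]
        n_inst <- sample(cl$motifs_per_element[1]:cl$motifs_per_element[2], 1L)
        motifs <- sample(cl$active_motifs, n_inst, replace = TRUE)
        for (mn in motifs) {
          m <- motif_library[[mn]]
          wm <- nrow(m$matrix)
          # non-overlapping placement within the element
          off <- NA_integer_
          for (t in 1:30) {
            cand <- as.integer(floor(runif(1) * (width - wm + 1L)))
            if (!length(el_occ_s) ||
                !any(cand < el_occ_e & cand + wm > el_occ_s)) {
              off <- cand; break
            }
          }
          if (is.na(off)) next # element full; planted count reflects reality
          strand <- if (runif(1) < 0.5) "+" else "-"
          inst <- sample_motif_instance(m, scan_thresholds[[mn]])
          if (strand == "-") inst <- rev_comp(inst)
          gstart <- pos_start[i] + off
          if (is.null(seq_chars[[pos_chrom[i]]]))
            seq_chars[[pos_chrom[i]]] <- strsplit(genome$seq[[pos_chrom[i]]], "")[[1]]
          seq_chars[[pos_chrom[i]]][(gstart + 1L):(gstart + wm)] <-
            strsplit(inst, "")[[1]]
          el_occ_s <- c(el_occ_s, off); el_occ_e <- c(el_occ_e, off + wm)
          truth[[length(truth) + 1L]] <- data.frame(
            chrom = pos_chrom[i], start = gstart, end = gstart + wm,
            strand = strand, motif = mn,
            element_id = elements$element_id[i], line = ln,
            stringsAsFactors = FALSE)
          signal[i] <- signal[i] + 1L
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), motif = character(),
                 element_id = character(), line = character())

    peaks <- lapply(line_names, function(ln) {
      sel <- vapply(assign_lines, function(a) ln %in% a, logical(1))
      d <- elements[sel, c("chrom", "start", "end"), drop = FALSE]
      d$name <- paste0(ln, "_", elements$element_id[sel])
      d$score <- 0L; d$strand <- "."
      d$signal <- as.numeric(signal[sel]); d$pvalue <- -1; d$qvalue <- -1
      d$summit <- -1L
      d <- .sort_intervals(d)
      rownames(d) <- NULL
      d
    })
    names(peaks) <- line_names

    seqs <- genome$seq
    for (chrom in ls(seq_chars))
      seqs[[chrom]] <- paste(seq_chars[[chrom]], collapse = "")

    list(genome = bench_genome(seqs, islands = genome$islands,
                               repeats = genome$repeats, spec = genome$spec),
         peaks = peaks, elements = elements, truth = truth)
  })
}

#' Jittered / thinned replicate of a peak set
#'
#' Emulates a second pooled experiment: each peak survives with
#' probability `1 - dropout_rate` and its center is shifted by a rounded
#' Normal(0, `jitter_sd`) offset (clamped inside the chromosome when
#' lengths are supplied).
#'
#' @param peaks data.frame of peaks
#' @param jitter_sd standard deviation of the center shift, bp (>= 0)
#' @param dropout_rate probability a peak is lost, in \[0, 1)
#' @param seed integer seed
#' @param chrom_lengths optional named lengths for clamping
#' @return data.frame of surviving, shifted peaks
#' @export
make_replicate <- function(peaks, jitter_sd = 0, dropout_rate = 0, seed = 1L,
                           chrom_lengths = NULL) {
  stopifnot(jitter_sd >= 0, dropout_rate >= 0, dropout_rate < 1)
  with_seed(seed, {
    n <- nrow(peaks)
    keep <- runif(n) >= dropout_rate
    out <- peaks[keep, , drop = FALSE]
    if (nrow(out)) {
      shift <- as.integer(round(rnorm(nrow(out), 0, jitter_sd)))
      out$start <- out$start + shift
      out$end <- out$end + shift
      if (!is.null(chrom_lengths)) {
        L <- chrom_lengths[as.character(out$chrom)]
        over <- pmax(out$end - L, 0L)
        out$start <- pmax(out$start - over, 0L)
        out$end <- pmin(out$end, L)
        under <- pmax(-out$start, 0L)
        out$start <- out$start + under
        out$end <- out$end + under
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Activity model for simulated reporter readouts
#'
#' Log2 activity of a fragment is linear in its motif density (scan hits
#' per bp) and GC fraction plus Gaussian noise:
#' `readout = intercept + beta_density * density + beta_gc * gc + N(0, noise_sd)`.
#' The positive GC coefficient mirrors the empirical positive correlation
#' of GC content with enhancer activity.
#'
#' @param intercept baseline log2 ratio
#' @param beta_density coefficient on motif density (per hit/bp)
#' @param beta_gc coefficient on GC fraction
#' @param noise_sd Gaussian noise SD in log2 units (>= 0; 0 makes the
#'   readout deterministic)
#' @param seed integer seed
#' @return an `activity_model`
#' @export
activity_model <- function(intercept = -0.5, beta_density = 150,
                           beta_gc = 2, noise_sd = 0.5, seed = 1L) {
  stopifnot(noise_sd >= 0)
  structure(list(intercept = intercept, beta_density = beta_density,
                 beta_gc = beta_gc, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "activity_model")
}

#' Simulate activity readouts for sequence fragments
#'
#' Motif density is measured by [scan_motifs()] at the default
#' log-odds threshold; GC is the fragment's GC fraction.
#'
#' @param fragments data.frame of fragment records with a `seq` column
#'   (and coordinates for bookkeeping)
#' @param model an [activity_model()]
#' @param motif_library a `motif_library` used for the density scan
#' @param scan_config a [motif_scan_config()]
#' @return `fragments` with added `density`, `gc` and `readout` columns
#' @export
simulate_activity <- function(fragments, model, motif_library,
                              scan_config = motif_scan_config()) {
  stopifnot(inherits(model, "activity_model"))
  scan <- scan_motifs(fragments$seq, motif_library, scan_config)
  width <- nchar(fragments$seq)
  density <- scan$per_record_hits / width
  gc <- gc_fraction(fragments$seq)
  readout <- with_seed(model$seed,
    model$intercept + model$beta_density * density + model$beta_gc * gc +
      rnorm(nrow(fragments), 0, model$noise_sd))
  fragments$density <- density
  fragments$gc <- gc
  fragments$readout <- readout
  fragments
}
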