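#' Benchmark orchestration
#'
#' [run_benchmark()] executes the whole study on a synthetic genome:
#' simulate genome and peaks, build both families of negative sets,
#' assemble chromosome hold-out datasets, train one classifier per
#' negative set, evaluate the three tasks (hold-out classification,
#' tissue-specific classification, quantitative activity), and run the
#' composition diagnostics. Every stage draws its seed deterministically
#' from the single global seed, so a rerun with an identical config
#' reproduces every number.
#' @name benchmark
NULL

.default_config <- function() {
  list(
    mode = "synthetic",
    seed = 1L,
    genome = list(
      chrom_lengths = c(chr1 = 1500000L, chr2 = 1500000L,
                        chr8 = 1000000L, chr21 = 800000L),
      background_gc = 0.41, gc_rich_island_rate = 12, island_gc = 0.62,
      island_length = 2000L, repeat_fraction = 0.10,
      repeat_block_length = 500L, cpg_depletion = 0.25,
      markov_order = 2L, chain_concentration = 5),
    motifs = list(n = 8L, widths = 8:12, dominance = 0.85),
    cell_lines = list(n_lines = 2L, peak_count = 500L,
                      motifs_per_line = 4L, shared_motifs = 2L,
                      motifs_per_element = c(2L, 6L), element_width = 300L,
                      shared_fraction = 0.3, island_element_fraction = 0.15,
                      target_lines = 1L),
    negatives = list(shuffle_k = c(2L, 7L), n_candidates = 20L,
                     overlap_k = 8L, t_gc = 0.02, batchsize = 10000L,
                     n_max_trials = 100L, min_match_rate = 0.80,
                     train_on = NULL),
    model = list(l = 6L, k = 4L, reverse_complement_collapse = TRUE,
                 normalization = "l2"),
    activity = list(intercept = -0.5, beta_density = 150, beta_gc = 2,
                    noise_sd = 0.5, fragment_width = 171L,
                    n_background_fragments = 150L),
    split = list(validation_chrom = "chr21", test_chrom = "chr8"),
    diagnostics = list(kmer_k = 8L, n_reference_windows = 10000L)
  )
}

.merge_config <- function(defaults, user, path = "") {
  errors <- character(0)
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(defaults)) {
      errors <- c(errors, paste0("unknown key: ", full))
      next
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      sub <- .merge_config(defaults[[nm]], as.list(user[[nm]]), full)
      defaults[[nm]] <- sub$config
      errors <- c(errors, sub$errors)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  list(config = defaults, errors = errors)
}

#' Validate and normalise a benchmark configuration
#'
#' Fills defaults, rejects unknown keys and range violations. The
#' configuration round-trips losslessly through JSON.
#'
#' @param x a named list of overrides, or the path to a JSON file of
#'   them; `NULL` gives the full default configuration
#' @return normalised configuration list (class `negbench_config`), or
#'   an error listing every problem found
#' @export
validate_config <- function(x = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  }
  if (is.null(x)) x <- list()
  merged <- .merge_config(.default_config(), x)
  cfg <- merged$config
  errors <- merged$errors
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(cfg$mode %in% c("synthetic", "real"), "mode must be 'synthetic' or 'real'")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed must be a scalar")
  chk(all(cfg$negatives$t_gc >= 0), "tolerance t_gc must be >= 0")
  chk(all(cfg$negatives$shuffle_k >= 1), "shuffle k must be >= 1")
  chk(cfg$negatives$min_match_rate > 0 && cfg$negatives$min_match_rate <= 1,
      "min_match_rate must be in (0, 1]")
  chk(cfg$genome$background_gc > 0 && cfg$genome$background_gc < 1,
      "background_gc must be in (0, 1)")
  chk(cfg$model$k >= 1 && cfg$model$k <= cfg$model$l,
      "model needs 1 <= k <= l")
  chk(cfg$cell_lines$n_lines >= 2, "need at least 2 cell lines")
  chk(all(cfg$cell_lines$target_lines >= 1 &
            cfg$cell_lines$target_lines <= cfg$cell_lines$n_lines),
      "target_lines must index existing cell lines")
  chk(cfg$cell_lines$shared_motifs < cfg$motifs$n,
      "shared_motifs must leave room for exclusive motifs")
  if (length(errors)) stop("invalid configuration:\n  ",
                           paste(errors, collapse = "\n  "))
  cl <- unlist(cfg$genome$chrom_lengths)
  cfg$genome$chrom_lengths <- setNames(as.integer(cl), names(cl))
  structure(cfg, class = "negbench_config")
}

#' Write a configuration to JSON
#' @param config a validated configuration
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  # named dict keeps chromosome names; NULLs (unset options) are omitted
  x$genome$chrom_lengths <- as.list(x$genome$chrom_lengths)
  drop_null <- function(l) {
    if (!is.list(l)) return(l)
    l <- l[!vapply(l, is.null, logical(1))]
    lapply(l, drop_null)
  }
  jsonlite::write_json(drop_null(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# partition motifs into per-line active sets: the first `shared` motifs
# are active everywhere, the rest are dealt round-robin
.assign_active_motifs <- function(motif_names, n_lines, per_line, shared) {
  excl <- setdiff(motif_names, motif_names[seq_len(shared)])
  lapply(seq_len(n_lines), function(i) {
    own <- excl[(seq_along(excl) - 1L) %% n_lines + 1L == i]
    c(motif_names[seq_len(shared)], head(own, per_line - shared))
  })
}

#' Simulate the full synthetic study world
#'
#' Genome, motif library, cell lines, planted peaks: the input side of
#' [run_benchmark()], exposed so tests and scripts can reuse it.
#'
#' @param config a validated configuration ([validate_config()])
#' @return list with `genome`, `library`, `cell_lines`, `peaks`,
#'   `elements`, `truth`
#' @export
simulate_world <- function(config = validate_config()) {
  g_spec <- do.call(genome_spec,
                    c(config$genome, list(seed = derive_seed(config$seed, "genome"))))
  genome <- generate_genome(g_spec)
  lib <- do.call(random_motif_library,
                 c(config$motifs, list(seed = derive_seed(config$seed, "motifs"))))
  cl_cfg <- config$cell_lines
  active <- .assign_active_motifs(names(lib), cl_cfg$n_lines,
                                  cl_cfg$motifs_per_line, cl_cfg$shared_motifs)
  lines <- lapply(seq_len(cl_cfg$n_lines), function(i)
    cell_line_model(name = sprintf("line%s", LETTERS[i]),
                    active_motifs = active[[i]],
                    peak_count = cl_cfg$peak_count,
                    motifs_per_element = cl_cfg$motifs_per_element,
                    element_width = cl_cfg$element_width))
  planted <- plant_elements(genome, lib, lines,
                            shared_fraction = cl_cfg$shared_fraction,
                            island_element_fraction = cl_cfg$island_element_fraction,
                            seed = derive_seed(config$seed, "plant"))
  list(genome = planted$genome, library = lib, cell_lines = lines,
       peaks = planted$peaks, elements = planted$elements,
       truth = planted$truth)
}

# train one classifier per negative set in `model_sets` and evaluate
# task 1 across every composition in `negsets` (record tables, presplit)
.holdout_eval <- function(pos_split, negsets, model_sets, model_cfg,
                          split_cfg) {
  gcfg <- do.call(gkm_config, model_cfg)
  models <- list()
  rows <- list()
  neg_splits <- lapply(negsets, chromosome_split,
                       validation_chrom = split_cfg$validation_chrom,
                       test_chrom = split_cfg$test_chrom)
  for (nm in names(model_sets)) {
    tr_neg <- neg_splits[[nm]]$train
    models[[nm]] <- train_gkm(
      pos_split$train$seq, tr_neg$seq, gcfg,
      validation = list(pos = pos_split$validation$seq,
                        neg = neg_splits[[nm]]$validation$seq))
  }
  for (nm in names(models)) {
    for (comp in names(negsets)) {
      te_neg <- neg_splits[[comp]]$test
      sc <- predict(models[[nm]], c(pos_split$test$seq, te_neg$seq))
      y <- c(rep(1L, nrow(pos_split$test)), rep(0L, nrow(te_neg)))
      rows[[paste(nm, comp)]] <- data.frame(
        task = "holdout", model = nm, test_composition = comp,
        auroc = auroc(sc, y)$value, auprc = auprc(sc, y)$value,
        recall = recall_at_threshold(sc, y)$value,
        n_pos = sum(y == 1L), n_neg = sum(y == 0L))
    }
  }
  list(models = models, metrics = do.call(rbind, rows))
}

#' Run the full negative-set benchmark
#'
#' See the module description above; returns every metric keyed by
#' model (negative training set) and test composition, plus the
#' composition diagnostics and a manifest of all effective parameters
#' and seeds.
#'
#' @param config a configuration from [validate_config()] (or overrides
#'   passed to it)
#' @return object of class `negbench_report`
#' @export
run_benchmark <- function(config = NULL) {
  if (!inherits(config, "negbench_config")) config <- validate_config(config)
  if (config$mode != "synthetic")
    stop("real mode requires external genome/peak/activity paths; ",
         "this entry point drives the synthetic study")
  world <- simulate_world(config)
  genome <- world$genome
  split_cfg <- config$split
  all_peaks <- do.call(rbind, lapply(world$peaks, `[`, c("chrom", "start", "end")))
  target_lines <- config$cell_lines$target_lines
  line_names <- vapply(world$cell_lines, `[[`, "", "name")

  metrics <- list()
  bg_reports <- list()
  diag_sets <- NULL # line-1 class sets, reused by the diagnostics below

  for (li in target_lines) {
    target <- line_names[li]
    positives <- filter_records(
      peaks_to_records(world$peaks[[target]], genome, label = 1L,
                       cell_line = target))
    pos_split <- chromosome_split(positives, split_cfg$validation_chrom,
                                  split_cfg$test_chrom)

    negsets <- list()
    for (k in config$negatives$shuffle_k) {
      scfg <- shuffle_config(k = k,
                             n_candidates = config$negatives$n_candidates,
                             overlap_k = config$negatives$overlap_k,
                             seed = derive_seed(config$seed,
                                                paste0(target, "_shuffle", k)))
      negsets[[paste0("shuffle_k", k)]] <- make_shuffle_negatives(positives, scfg)
    }
    for (t_gc in config$negatives$t_gc) {
      bcfg <- background_config(t_gc = t_gc,
                                batchsize = config$negatives$batchsize,
                                n_max_trials = config$negatives$n_max_trials,
                                min_match_rate = config$negatives$min_match_rate,
                                seed = derive_seed(config$seed,
                                                   paste0(target, "_bg", t_gc)))
      bg <- sample_matched_background(genome, positives, all_peaks, bcfg)
      nm <- paste0("background_t", t_gc)
      bg_reports[[paste0(target, "_", nm)]] <- bg$report
      ds <- balanced_dataset(positives, bg)
      negsets[[nm]] <- ds[ds$label == 0L, , drop = FALSE]
    }
    if (li == target_lines[1L])
      diag_sets <- c(list(positives = positives), negsets)

    train_on <- config$negatives$train_on
    model_sets <- if (length(train_on)) negsets[intersect(train_on, names(negsets))]
                  else negsets
    hold <- .holdout_eval(pos_split, negsets, model_sets, config$model,
                          split_cfg)
    rows <- hold$metrics

    # --- task 2: tissue-specific -----------------------------------------
    tissue <- build_tissue_specific_sets(world$peaks, target, genome,
                                         validation_chrom = split_cfg$validation_chrom,
                                         test_chrom = split_cfg$test_chrom)
    for (nm in names(hold$models)) {
      te <- tissue$test
      sc <- predict(hold$models[[nm]], c(te$positives$seq, te$negatives$seq))
      y <- c(rep(1L, nrow(te$positives)), rep(0L, nrow(te$negatives)))
      rows <- rbind(rows, data.frame(
        task = "tissue", model = nm, test_composition = "tissue_specific",
        auroc = auroc(sc, y)$value, auprc = auprc(sc, y)$value,
        recall = recall_at_threshold(sc, y)$value,
        n_pos = sum(y == 1L), n_neg = sum(y == 0L)))
    }

    # --- task 3: quantitative activity -----------------------------------
    act_cfg <- config$activity
    frag <- .activity_fragments(world, config, target)
    amodel <- activity_model(act_cfg$intercept, act_cfg$beta_density,
                             act_cfg$beta_gc, act_cfg$noise_sd,
                             seed = derive_seed(config$seed, "activity"))
    frag <- simulate_activity(frag, amodel, world$library)
    act_rows <- list()
    for (nm in names(hold$models)) {
      sc <- predict(hold$models[[nm]], frag$seq)
      rho <- spearman(sc, frag$readout)$value
      act_rows[[nm]] <- data.frame(
        task = "activity", model = nm, test_composition = "mpra_fragments",
        auroc = NA_real_, auprc = NA_real_, recall = NA_real_,
        n_pos = nrow(frag), n_neg = 0L)
      act_rows[[nm]]$spearman <- rho
    }
    rows$spearman <- NA_real_
    rows <- rbind(rows, do.call(rbind, act_rows))
    rows <- cbind(line = target, rows)
    metrics[[target]] <- rows
    if (li == target_lines[1L])
      activity_table <- frag[, c("id", "chrom", "start", "end",
                                 "density", "gc", "readout")]
  }
  metrics <- do.call(rbind, metrics)

  # --- diagnostics (line 1 sets) -----------------------------------------
  diag_cfg <- config$diagnostics
  ktab <- build_kmer_table(genome, k = diag_cfg$kmer_k)
  z_by_class <- vapply(diag_sets,
                       function(d) sequence_kmer_zscores(d$seq, ktab)$mean_z,
                       numeric(1))
  motif_rate <- vapply(diag_sets,
                       function(d) scan_motifs(d$seq, world$library)$motifs_per_300bp[["mean"]],
                       numeric(1))
  ref <- random_windows(genome, diag_cfg$n_reference_windows,
                        width = world$cell_lines[[1L]]$element_width,
                        seed = derive_seed(config$seed, "refwin"))
  gc_sets <- c(diag_sets[1L], list(genome_reference = ref), diag_sets[-1L])
  gcd <- gc_distribution(gc_sets,
                         ks_pairs = lapply(names(diag_sets)[-1L], function(nm)
                           c("positives", nm)))

  manifest <- list(config = unclass(config),
                   seeds = list(global = config$seed),
                   background_reports = lapply(bg_reports, function(r)
                     r[c("match_rate", "n_matched", "n_positives")]))
  rownames(metrics) <- NULL
  structure(list(metrics = metrics,
                 diagnostics = list(kmer_z_by_class = z_by_class,
                                    motifs_per_300bp = motif_rate,
                                    gc = gcd[c("histograms", "ks")]),
                 activity = activity_table,
                 manifest = manifest),
            class = "negbench_report")
}

# activity fragments: target-line elements plus background windows, at the
# assay fragment width, then extended to the element width
.activity_fragments <- function(world, config, target) {
  act_cfg <- config$activity
  test_chrom <- config$split$test_chrom
  peaks <- world$peaks[[target]]
  peaks <- peaks[peaks$chrom == test_chrom, , drop = FALSE]
  w <- act_cfg$fragment_width
  center <- (peaks$start + peaks$end) %/% 2L
  frag <- data.frame(chrom = peaks$chrom,
                     start = center - w %/% 2L,
                     end = center - w %/% 2L + w)
  bgw <- random_windows(world$genome, act_cfg$n_background_fragments * 3L,
                        width = w,
                        seed = derive_seed(config$seed, "actbg"))
  # keep background fragments clear of any peak
  cov <- interval_covered_by(bgw, do.call(rbind, lapply(world$peaks, `[`,
                                                        c("chrom", "start", "end"))))
  bgw <- bgw[cov == 0, , drop = FALSE]
  bgw <- head(bgw, act_cfg$n_background_fragments)
  frag <- rbind(frag, bgw[, c("chrom", "start", "end")])
  frag$readout <- NA_real_
  prepare_activity_fragments(frag, world$genome,
                             target_width = world$cell_lines[[1L]]$element_width)
}

#' @export
print.negbench_report <- function(x, ...) {
  cat("<negbench_report>\n")
  print(x$metrics, digits = 3)
  cat("\nmean genome 8-mer Z by class:\n")
  print(round(x$diagnostics$kmer_z_by_class, 3))
  cat("\nmotif matches per 300 bp by class:\n")
  print(round(x$diagnostics$motifs_per_300bp, 2))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Metrics as TSV, diagnostics and manifest as JSON.
#' @param report a `negbench_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$metrics, file.path(dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(kmer_z_by_class = as.list(report$diagnostics$kmer_z_by_class),
                            motifs_per_300bp = as.list(report$diagnostics$motifs_per_300bp),
                            gc_ks = as.list(report$diagnostics$gc$ks)),
                       file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
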