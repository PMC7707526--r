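#' Gapped k-mer featurization and linear sequence classifiers
#'
#' Sequences are represented by counts of gapped k-mers: length-`l`
#' words with `k` informative positions and `l - k` wildcard gaps. Every
#' window of each sequence contributes one token per informative-position
#' mask, so each sequence yields `(L - l + 1) * C(l, k)` token counts
#' over a space of `C(l, k) * 4^k` features. A regularised linear
#' logistic model over these explicit counts is the reference learner;
#' it keeps the gapped k-mer feature space of gkm-SVMs while remaining
#' exactly testable.
#' @name gkm
NULL

#' Gapped k-mer feature configuration
#'
#' @param l word length (default 10)
#' @param k informative columns (default 6); `1 <= k <= l <= 12`
#' @param reverse_complement_collapse map each token and its reverse
#'   complement to one canonical feature (default TRUE: DNA strands are
#'   interchangeable)
#' @param normalization `"l2"` (rows scaled to unit norm before model
#'   fitting) or `"none"`
#' @return a `gkm_config`
#' @export
gkm_config <- function(l = 10L, k = 6L, reverse_complement_collapse = TRUE,
                       normalization = c("l2", "none")) {
  normalization <- match.arg(normalization)
  l <- as.integer(l); k <- as.integer(k)
  if (k < 1L || k > l || l > 12L)
    stop("need 1 <= k <= l <= 12")
  structure(list(l = l, k = k,
                 reverse_complement_collapse = reverse_complement_collapse,
                 normalization = normalization,
                 n_features = choose(l, k) * 4^k),
            class = "gkm_config")
}

#' Featurize sequences as gapped k-mer counts
#'
#' @param seqs character vector of DNA sequences (uppercased internally;
#'   tokens touching a non-ACGT character are skipped). Sequences shorter
#'   than `l` produce an empty row, with a warning.
#' @param config a [gkm_config()]
#' @return sparse `dgCMatrix`, one row per sequence,
#'   `C(l, k) * 4^k` columns
#' @export
gkm_featurize <- function(seqs, config = gkm_config()) {
  if (any(nchar(seqs) < config$l))
    warning(sum(nchar(seqs) < config$l),
            " sequence(s) shorter than l = ", config$l, ": empty feature rows")
  masks <- combn(config$l, config$k)
  trip <- cpp_gkm_featurize(toupper(seqs), masks, config$l, config$k,
                            config$reverse_complement_collapse)
  Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                       dims = c(length(seqs), trip$nfeat))
}

.row_l2_normalize <- function(x) {
  nrm <- sqrt(Matrix::rowSums(x^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% x
}

#' Train a linear gapped k-mer classifier
#'
#' Ridge-regularised logistic regression over gapped k-mer counts
#' (fitted by glmnet). The regularisation strength is taken from a fixed
#' small grid: when a validation set is supplied the grid value with the
#' best validation AUROC is kept, otherwise the default mid-grid value
#' is used. Training is deterministic given its inputs.
#'
#' @param pos_seqs,neg_seqs character vectors of training sequences
#'   (at least 10 per class)
#' @param config a [gkm_config()]
#' @param lambda optional fixed regularisation strength, overriding the
#'   grid
#' @param validation optional list with `pos` and `neg` sequence vectors
#'   for grid selection
#' @return object of class `gkm_classifier`
#' @export
train_gkm <- function(pos_seqs, neg_seqs, config = gkm_config(),
                      lambda = NULL, validation = NULL) {
  if (length(pos_seqs) < 10L || length(neg_seqs) < 10L)
    stop("need at least 10 records per class")
  x <- gkm_featurize(c(pos_seqs, neg_seqs), config)
  if (config$normalization == "l2") x <- .row_l2_normalize(x)
  y <- c(rep(1L, length(pos_seqs)), rep(0L, length(neg_seqs)))
  grid <- if (!is.null(lambda)) lambda else c(1, 0.1, 0.01, 0.001)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = grid, standardize = FALSE)
  chosen <- if (!is.null(lambda)) lambda[1L]
  else if (!is.null(validation)) {
    xv <- gkm_featurize(c(validation$pos, validation$neg), config)
    if (config$normalization == "l2") xv <- .row_l2_normalize(xv)
    yv <- c(rep(1L, length(validation$pos)), rep(0L, length(validation$neg)))
    sc <- stats::predict(fit, xv, s = grid)
    perf <- apply(sc, 2L, function(s) auroc(s, yv)$value)
    grid[which.max(perf)]
  } else 0.01
  beta <- stats::coef(fit, s = chosen)
  structure(list(
    intercept = beta[1L],
    beta = Matrix::Matrix(beta[-1L, , drop = FALSE], sparse = TRUE),
    config = config, lambda = chosen, lambda_grid = grid,
    n_pos = length(pos_seqs), n_neg = length(neg_seqs),
    converged = all(fit$npasses < fit$call$maxit %||% 1e5)),
    class = "gkm_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gkm_classifier <- function(x, ...) {
  cat(sprintf(
    "<gkm_classifier> l = %d, k = %d, %s features; trained on %d pos / %d neg (lambda = %g)\n",
    x$config$l, x$config$k,
    format(x$config$n_features, big.mark = ","), x$n_pos, x$n_neg, x$lambda))
  invisible(x)
}

#' @export
summary.gkm_classifier <- function(object, ...) {
  nz <- Matrix::nnzero(object$beta)
  cat(sprintf("Linear gapped k-mer classifier (l = %d, k = %d)\n",
              object$config$l, object$config$k))
  cat(sprintf("  features: %s (%s non-zero weights)\n",
              format(object$config$n_features, big.mark = ","),
              format(nz, big.mark = ",")))
  cat(sprintf("  training: %d positives, %d negatives; ridge lambda = %g\n",
              object$n_pos, object$n_neg, object$lambda))
  cat(sprintf("  intercept: %.4f\n", object$intercept))
  invisible(object)
}

#' @export
coef.gkm_classifier <- function(object, ...) {
  c(intercept = object$intercept,
    setNames(as.numeric(object$beta), NULL))
}

#' Score sequences with a trained classifier
#'
#' @param object a `gkm_classifier`
#' @param seqs character vector of sequences
#' @param type `"prob"` (logistic link, in (0,1)) or `"margin"` (raw
#'   linear score)
#' @param ... unused
#' @return numeric vector of scores, one per sequence (sequences shorter
#'   than `l` receive the intercept-only score, with the featurizer's
#'   warning)
#' @export
predict.gkm_classifier <- function(object, seqs, type = c("prob", "margin"),
                                   ...) {
  type <- match.arg(type)
  x <- gkm_featurize(seqs, object$config)
  if (object$config$normalization == "l2") x <- .row_l2_normalize(x)
  margin <- as.numeric(x %*% object$beta) + object$intercept
  if (type == "margin") margin else 1 / (1 + exp(-margin))
}

#' Train replicate models and keep the median performer
#'
#' Repeats training `n_replicates` times with seeds `seed + 0 ...
#' seed + n - 1` and returns the replicate whose validation metric is
#' the median (lower median for even n; ties broken by the lowest
#' replicate index), together with the full metric table. With a
#' deterministic learner all replicates coincide and replicate 1 is
#' selected.
#'
#' @param train_fn function(seed) returning a fitted model
#' @param validate_fn function(model) returning a scalar validation
#'   metric (higher is better)
#' @param n_replicates number of replicates (default 10)
#' @param seed base seed
#' @return list with `model`, `selected` (replicate index), `metrics`
#' @export
train_replicates <- function(train_fn, validate_fn, n_replicates = 10L,
                             seed = 1L) {
  models <- vector("list", n_replicates)
  metrics <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    models[[i]] <- with_seed(seed + i - 1L, train_fn(seed + i - 1L))
    metrics[i] <- validate_fn(models[[i]])
  }
  ord <- order(metrics, seq_len(n_replicates)) # stable: lowest index first
  med_pos <- ord[floor((n_replicates + 1) / 2)]
  # among replicates with the median value, pick the lowest index
  med_val <- metrics[med_pos]
  selected <- which(metrics == med_val)[1L]
  list(model = models[[selected]], selected = selected, metrics = metrics)
}
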