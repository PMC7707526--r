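#' Performance metrics
#'
#' The measures used across the three evaluation tasks: AUROC and AUPRC
#' with their curves, recall at a probability threshold, Spearman rank
#' correlation for quantitative activity, and the Wilcoxon signed-rank
#' test for paired model comparisons. All results are returned as
#' `metric_result` objects carrying the value, sample sizes, curve
#' points where applicable and the tie/threshold policies used.
#' @name metrics
NULL

metric_result <- function(metric, value, ..., curve = NULL, parameters = list()) {
  structure(c(list(metric = metric, value = value, curve = curve,
                   parameters = parameters), list(...)),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result> %s = %s\n", x$metric,
              format(x$value, digits = 4)))
  invisible(x)
}

.check_binary <- function(labels) {
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
}

#' Area under the ROC curve
#'
#' Equals the Mann-Whitney probability P(score_pos > score_neg) +
#' 0.5 P(tie), computed from mid-ranks; the curve is the score-sorted
#' sweep with tied scores collapsed to one threshold.
#'
#' @param scores numeric prediction scores (any monotone scale)
#' @param labels 0/1 class labels
#' @return a `metric_result` with `value`, `n_pos`, `n_neg` and the ROC
#'   `curve` (fpr, tpr)
#' @export
auroc <- function(scores, labels) {
  .check_binary(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  r <- rank(scores) # mid-ranks handle ties with the 1/2 convention
  value <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s)) # tie groups share a threshold
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  curve <- data.frame(fpr = c(0, fp[last] / n_neg), tpr = c(0, tp[last] / n_pos))
  metric_result("AUROC", value, n_pos = n_pos, n_neg = n_neg, curve = curve,
                parameters = list(tie_policy = "half"))
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step area: precision at each achievable recall level
#' (tied scores collapsed), summed over recall increments. A perfect
#' ranking gives 1; random scores give the positive-class prevalence in
#' expectation.
#'
#' @inheritParams auroc
#' @return a `metric_result` with the PR `curve` (recall, precision)
#' @export
auprc <- function(scores, labels) {
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("no positive samples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); n_pred <- seq_along(y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  recall <- tp[last] / n_pos
  precision <- tp[last] / n_pred[last]
  d_recall <- diff(c(0, recall))
  value <- sum(precision * d_recall)
  curve <- data.frame(recall = recall, precision = precision)
  metric_result("AUPRC", value, n_pos = n_pos, n_neg = sum(labels == 0L),
                curve = curve,
                parameters = list(interpolation = "step"))
}

#' Recall at a probability threshold
#'
#' TP / (TP + FN) with a prediction called positive when its score is at
#' least `threshold` (default 0.5 on the probability scale).
#'
#' @inheritParams auroc
#' @param threshold decision threshold (recorded in the result)
#' @return a `metric_result`
#' @export
recall_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("no positive samples")
  tp <- sum(scores >= threshold & labels == 1L)
  metric_result("recall", tp / n_pos, n_pos = n_pos,
                n_neg = sum(labels == 0L),
                parameters = list(threshold = threshold))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties). A constant
#' input vector makes the correlation undefined; the result is flagged
#' and its value is NA.
#'
#' @param predictions,readouts paired numeric vectors (n >= 3)
#' @return a `metric_result` with `n_pairs` and a `degenerate` flag
#' @export
spearman <- function(predictions, readouts) {
  ok <- is.finite(predictions) & is.finite(readouts)
  x <- predictions[ok]; y <- readouts[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(metric_result("spearman_rho", NA_real_, n_pairs = length(x),
                         degenerate = TRUE,
                         parameters = list(tie_policy = "average_rank")))
  }
  value <- cor(x, y, method = "spearman")
  metric_result("spearman_rho", value, n_pairs = length(x), degenerate = FALSE,
                parameters = list(tie_policy = "average_rank"))
}

# exact null distribution of the signed-rank statistic T+ given the
# (doubled, integer) ranks of the non-zero |differences|
.signed_rank_tail <- function(ranks2, t2) {
  # distribution of sum of a random subset: polynomial product of
  # (1 + x^r)/2 over ranks
  total <- sum(ranks2)
  dist <- numeric(total + 1L)
  dist[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1L - r)])
    dist <- (dist + shifted) / 2
  }
  p_le <- sum(dist[seq_len(t2 + 1L)])
  p_ge <- sum(dist[(t2 + 1L):(total + 1L)])
  c(p_le = p_le, p_ge = p_ge)
}

#' Wilcoxon signed-rank test for paired performance comparisons
#'
#' Zero differences are dropped (and counted); |differences| are ranked
#' with average ranks. For n <= `exact_max` pairs the two-sided p-value
#' is exact — the full 2^n sign-assignment null, evaluated by dynamic
#' programming so ties are handled exactly — otherwise a normal
#' approximation with continuity and tie correction is used.
#'
#' @param a,b paired numeric vectors
#' @param exact_max largest n for the exact null (default 25)
#' @return a `metric_result` with `statistic` (T+ = sum of ranks of
#'   positive differences), `n_pairs` (non-zero pairs), `n_zero`,
#'   `wilcoxon_p` as value, and a `degenerate` flag when all differences
#'   are zero (no p-value)
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25L) {
  d <- a - b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(metric_result("wilcoxon_p", NA_real_, statistic = NA_real_,
                         n_pairs = 0L, n_zero = n_zero, degenerate = TRUE,
                         parameters = list(method = "none")))
  }
  if (n < 5L) stop("need at least 5 non-zero paired differences")
  r <- rank(abs(d))
  tplus <- sum(r[d > 0])
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    t2 <- as.integer(round(2 * tplus))
    tails <- .signed_rank_tail(ranks2, t2)
    p <- min(1, 2 * min(tails))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (tplus - mu - sign(tplus - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_cc"
  }
  metric_result("wilcoxon_p", p, statistic = tplus, n_pairs = n,
                n_zero = n_zero, degenerate = FALSE,
                parameters = list(method = method))
}
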