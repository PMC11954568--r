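#' Ranking and threshold metrics for binary interaction scores
#'
#' Computes AUC (rank statistic with tie averaging), AUPR (step-interpolated
#' precision-recall, i.e. precision at each achieved recall level), and the
#' thresholded confusion metrics ACC, Precision, Recall and F1.
#'
#' @param scores numeric vector of predicted scores.
#' @param labels 0/1 vector of the same length, containing at least one
#'   positive and one negative.
#' @param threshold classification cut-off (default 0.5).
#' @return an object of class \code{"metric_report"}: a named numeric
#'   vector with elements \code{auc}, \code{aupr}, \code{f1}, \code{acc},
#'   \code{precision}, \code{recall}.
#' @examples
#' evaluate_scores(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop("need at least one positive and one negative label", call. = FALSE)

  # AUC via the Mann-Whitney rank statistic, ties averaged
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)

  aupr <- step_aupr(scores, labels)

  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  acc <- (tp + tn) / length(labels)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0

  structure(c(auc = auc, aupr = aupr, f1 = f1, acc = acc,
              precision = prec, recall = rec),
            class = "metric_report")
}

# Area under the precision-recall curve with step interpolation: sweep the
# distinct score thresholds in decreasing order, take precision at each
# achieved recall level, and sum precision * delta-recall.
step_aupr <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate at the last index of each tied score block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  np <- sum(labels == 1)
  recall <- tp / np
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(paste(sprintf("%s %.4f", toupper(names(x)), unclass(x)),
            collapse = " | "), "\n")
  invisible(x)
}

#' Benchmark dataset pair arithmetic
#'
#' Bookkeeping for how a binary DTI corpus is assembled from its entity
#' counts and positive interactions: the all-pairs total, and the negative
#' count under either labeling rule — \code{"all_unknown"} (every
#' non-positive pair is a negative, as in affinity-thresholded corpora) or
#' \code{"sampled"} (negatives drawn from unknown pairs at
#' \code{ratio} per positive, the balanced setting).
#'
#' @param n_drugs,n_proteins entity counts.
#' @param n_positives number of positive interactions.
#' @param negative_rule \code{"all_unknown"} or \code{"sampled"}.
#' @param ratio negatives per positive under the sampled rule.
#' @param n_measured number of assayed pairs for the all-unknown rule;
#'   defaults to every drug-protein combination (exhaustive assays).
#' @return named list: \code{all_pairs}, \code{positives},
#'   \code{negatives}, \code{interactions} (positives + negatives).
#' @examples
#' dti_dataset_stats(68, 379, 7320, "all_unknown")   # exhaustive affinity assay
#' dti_dataset_stats(6647, 4294, 17511, "sampled")   # balanced corpus
#' @export
dti_dataset_stats <- function(n_drugs, n_proteins, n_positives,
                              negative_rule = c("sampled", "all_unknown"),
                              ratio = 1, n_measured = NULL) {
  negative_rule <- match.arg(negative_rule)
  all_pairs <- as.numeric(n_drugs) * as.numeric(n_proteins)
  if (is.null(n_measured)) n_measured <- all_pairs
  if (n_measured > all_pairs)
    stop("more measured pairs than drug-protein pairs", call. = FALSE)
  if (n_positives > n_measured)
    stop("more positives than drug-protein pairs", call. = FALSE)
  negatives <- switch(negative_rule,
    all_unknown = n_measured - n_positives,
    sampled = floor(ratio * n_positives))
  list(all_pairs = all_pairs, positives = n_positives,
       negatives = negatives, interactions = n_positives + negatives)
}
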