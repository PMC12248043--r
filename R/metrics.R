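# Agreement and ranking metrics used by the benchmark module. All are
# implemented from their contingency-table / rank definitions so they can
# serve as fixed reference points for the evaluation suite.

#' Adjusted Rand index
#'
#' @param a,b two label vectors over the same items.
#' @return ARI in (-1, 1\]; 1 iff the partitions coincide.
#' @export
adjusted_rand_index <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(ct)
  e1 <- sum_comb(rowSums(ct)); e2 <- sum_comb(colSums(ct))
  expected <- e1 * e2 / choose(n, 2)
  maxi <- (e1 + e2) / 2
  if (maxi == expected) return(0)
  (idx - expected) / (maxi - expected)
}

#' Normalized mutual information (arithmetic normalization)
#'
#' `I(a; b) / mean(H(a), H(b))`; 0 for independent partitions, 1 for
#' identical ones.
#'
#' @param a,b two label vectors over the same items.
#' @return NMI in \[0, 1\].
#' @export
normalized_mutual_info <- function(a, b) {
  ct <- table(a, b) / length(a)
  pa <- rowSums(ct); pb <- colSums(ct)
  nz <- ct > 0
  mi <- sum(ct[nz] * log(ct[nz] / outer(pa, pb)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- (h(pa) + h(pb)) / 2
  if (denom == 0) return(if (mi == 0) 1 else 0)
  max(0, min(1, mi / denom))
}

#' Macro-averaged F1 after majority-vote cluster labeling
#'
#' Each cluster is mapped to its most frequent truth label (ties broken
#' lexicographically), then per-class F1 is averaged over the truth
#' classes; a class never predicted scores 0.
#'
#' @param clusters cluster assignments.
#' @param truth ground-truth labels.
#' @return list: `macro_f1`, `mapped` (per-item predicted labels).
#' @export
macro_f1_voting <- function(clusters, truth) {
  clusters <- as.character(clusters); truth <- as.character(truth)
  map <- vapply(split(truth, clusters), function(tt) {
    tab <- sort(table(tt), decreasing = TRUE)
    nm <- names(tab)[tab == max(tab)]
    sort(nm)[1]
  }, character(1))
  pred <- unname(map[clusters])
  classes <- sort(unique(truth))
  f1s <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(macro_f1 = mean(f1s), mapped = pred)
}

#' Rank-based AUROC
#'
#' Mann-Whitney formulation with ties averaged: the probability that a
#' random positive outscores a random negative (ties count half).
#' Invariant to any strictly monotone transform of the scores.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) positive-class indicators.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("AUROC needs both positive and negative examples")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral: precision is averaged at the rank of each positive,
#' descending-score order. Tied scores are processed as a block so the
#' result does not depend on the order within ties.
#'
#' @param scores numeric scores.
#' @param labels positive-class indicators.
#' @return AUPRC in \[0, 1\]; equals the positive prevalence for
#'   uninformative scores in expectation.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0) stop("AUPRC needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # block ties: cumulative tp/fp evaluated at the end of each tie block,
  # positives inside a block get that block-end precision
  blocks <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  block_end <- !duplicated(blocks, fromLast = TRUE)
  tp_end <- tp[block_end][blocks]; fp_end <- fp[block_end][blocks]
  prec_at <- tp_end / (tp_end + fp_end)
  sum(prec_at[y]) / n_pos
}
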