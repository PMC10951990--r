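#' Classification metrics for a gene score table
#'
#' Accuracy and F1 are computed at the probability threshold (default 0.5);
#' AUROC via the rank-based Mann-Whitney U statistic (tie-aware) and AUPRC
#' as average precision with step interpolation. Only labeled genes enter.
#'
#' @param scores Named numeric vector of per-gene probabilities.
#' @param labels A \code{\link{label_set}}.
#' @param threshold Decision threshold for accuracy/F1.
#' @return List of class \code{eval_report}: \code{accuracy}, \code{auroc},
#'   \code{auprc}, \code{f1}, \code{n_pos}, \code{n_neg}.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5) {
  pos <- intersect(names(scores), labels$positives)
  neg <- intersect(names(scores), labels$negatives)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present among scored genes")
  s <- scores[c(pos, neg)]
  y <- c(rep(1L, length(pos)), rep(0L, length(neg)))

  pred <- as.integer(s > threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  accuracy <- mean(pred == y)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)

  # AUROC: U statistic from mid-ranks (handles score ties)
  r <- rank(s)
  auroc <- (sum(r[y == 1L]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))

  # AUPRC: average precision, deterministic tie-break by gene ID
  ord <- order(-s, names(s))
  ys <- y[ord]
  prec <- cumsum(ys) / seq_along(ys)
  auprc <- sum(prec[ys == 1L]) / length(pos)

  structure(list(accuracy = accuracy, auroc = auroc, auprc = auprc, f1 = f1,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  AUROC %.4f  AUPRC %.4f  F1 %.4f  (%d+/%d-)\n",
              x$accuracy, x$auroc, x$auprc, x$f1, x$n_pos, x$n_neg))
  invisible(x)
}

#' Rank labeled genes by score
#'
#' Unlabeled genes are dropped. The ordering is strict: score descending,
#' ties broken by gene ID ascending.
#'
#' @param scores Named numeric vector of gene scores.
#' @param labels A \code{\link{label_set}}.
#' @return Data frame (gene, score, label) ordered best-first; label is
#'   \code{"positive"} or \code{"negative"}.
#' @export
rank_genes <- function(scores, labels) {
  pos <- intersect(names(scores), labels$positives)
  neg <- intersect(names(scores), labels$negatives)
  df <- data.frame(gene = c(pos, neg),
                   score = unname(scores[c(pos, neg)]),
                   label = rep(c("positive", "negative"),
                               c(length(pos), length(neg))),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Partial ROC statistic AUCn
#'
#' \deqn{AUC_n = \frac{1}{nT} \sum_{i=1}^{n} T_i} where \eqn{T} is the
#' total number of positives and \eqn{T_i} the number of positives ranked
#' strictly above the i-th highest-ranked negative. Sensitive to the very
#' top of the ranking, where prioritized genes are actually inspected.
#'
#' @param ranked A ranking from \code{\link{rank_genes}} (or any data frame
#'   with \code{label} in ranked order, best first).
#' @param n Number of top-ranked negatives to average over.
#' @return AUCn in \[0, 1\].
#' @export
auc_n <- function(ranked, n) {
  lab <- ranked$label
  total_pos <- sum(lab == "positive")
  neg_pos_in_rank <- which(lab == "negative")
  if (total_pos == 0L) stop("no positives in ranking")
  if (length(neg_pos_in_rank) < n)
    stop("ranking has ", length(neg_pos_in_rank),
         " negatives, fewer than n = ", n)
  pos_above <- cumsum(lab == "positive")
  Ti <- pos_above[neg_pos_in_rank[seq_len(n)]]
  sum(Ti) / (n * total_pos)
}
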