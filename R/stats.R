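#' Area under the ROC curve by rank statistic
#'
#' Computes AUROC as the normalized Mann-Whitney U statistic: the
#' probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted as one half.
#'
#' @param scores numeric predicted scores.
#' @param labels 0/1 (or logical) outcome labels; both classes required.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: test set contains a single class", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Threshold classification metrics
#'
#' Precision, recall and F1 of \code{scores >= threshold} against 0/1
#' labels. Precision of an all-negative prediction and F1 with empty
#' support are reported as \code{NA}.
#'
#' @param scores numeric predicted probabilities.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return named numeric vector \code{precision}, \code{recall}, \code{f1}.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(precision = precision, recall = recall, f1 = f1)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two samples by the rank-sum statistic of the first sample over
#' the pooled midranks. For combined sample size at most \code{exact_max}
#' the null distribution is obtained by full enumeration of all
#' \code{choose(n1 + n2, n1)} group assignments of the pooled values (valid
#' under ties), and the two-sided p value is
#' \code{min(1, 2 * min(P(W <= w), P(W >= w)))}. Larger samples use the
#' normal approximation with midrank tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_max maximum combined size for the exact branch (default 10).
#' @return list with \code{p.value}, \code{statistic} (rank sum of
#'   \code{x}) and \code{method} ("exact" or "normal").
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  n <- n1 + n2
  if (n <= exact_max) {
    idx <- utils::combn(n, n1)
    ws <- colSums(matrix(r[idx], nrow = n1))
    p <- min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
    return(list(p.value = p, statistic = w, method = "exact"))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0)  # all values tied
    return(list(p.value = 1, statistic = w, method = "normal"))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  list(p.value = min(1, 2 * pnorm(-abs(z))), statistic = w, method = "normal")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment: ordered p values are multiplied by \code{m/rank}
#' and a cumulative minimum from the largest p downward enforces
#' monotonicity; q values are capped at 1. Features with \code{q <= alpha}
#' are flagged significant.
#'
#' @param p numeric vector of p values in [0, 1] (\code{NA} allowed and
#'   propagated).
#' @param alpha significance level for the flags (default 0.05).
#' @return list with \code{q} (adjusted values, same order as input) and
#'   \code{significant} (logical flags).
#' @export
fdr_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m) {
    ord <- order(p[ok])
    ranked <- p[ok][ord] * m / seq_len(m)
    ranked <- rev(cummin(rev(ranked)))
    qq <- numeric(m)
    qq[ord] <- pmin(1, ranked)
    q[ok] <- qq
  }
  list(q = q, significant = !is.na(q) & q <= alpha)
}
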