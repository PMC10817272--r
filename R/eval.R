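#' Split samples into train / validation / test sets
#'
#' Seeded shuffle followed by an 8:1:1 partition: \code{floor(0.8 n)}
#' training, \code{floor(0.1 n)} validation, remainder test. Every sample
#' falls in exactly one split; with one sample per patient this is a
#' patient-level split.
#'
#' @param n number of samples (>= 10), or a vector whose length is used.
#' @param ratios positive weights for train/validation/test (default
#'   \code{c(8, 1, 1)}).
#' @param seed integer seed for the shuffle.
#' @return list with integer index vectors \code{train},
#'   \code{validation}, \code{test}.
#' @export
split_samples <- function(n, ratios = c(8, 1, 1), seed = 1L) {
  if (length(n) > 1) n <- length(n)
  if (n < 10) stop("need at least 10 samples to split 8:1:1", call. = FALSE)
  stopifnot(length(ratios) == 3, all(ratios > 0))
  set.seed(seed)
  ord <- sample.int(n)
  f <- ratios / sum(ratios)
  n_train <- floor(f[1] * n)
  n_val <- floor(f[2] * n)
  list(train = sort(ord[seq_len(n_train)]),
       validation = sort(ord[n_train + seq_len(n_val)]),
       test = sort(ord[(n_train + n_val + 1):n]))
}

#' Evaluate a fitted model on a test set
#'
#' @param object a \code{seqrisk_model}.
#' @param data an \code{encoded_cohort}.
#' @param indices sample indices to evaluate (defaults to the model's test
#'   split).
#' @param threshold classification threshold for precision/recall/F1.
#' @return named numeric vector with \code{auroc}, \code{precision},
#'   \code{recall}, \code{f1}.
#' @export
evaluate_model <- function(object, data, indices = NULL, threshold = 0.5) {
  if (is.null(indices)) indices <- object$split$test
  p <- predict(object, data, indices = indices)
  y <- data$labels[indices]
  c(auroc = auroc(p, y), classification_metrics(p, y, threshold))
}

#' Repeat the fit/evaluate pipeline and aggregate metrics
#'
#' Re-runs [seqrisk_fit()] \code{k} times with jointly re-randomized split
#' and initialization seeds, and reports per-repeat validation AUROC, test
#' AUROC, test precision, recall and F1 together with their mean and sample
#' (n-1) standard deviation.
#'
#' @param data an \code{encoded_cohort}.
#' @param model \code{"tlstm"}, \code{"retain"} or \code{"lr"}.
#' @param k number of repeats (default 5, >= 2).
#' @param config a [model_config()]; per-repeat seeds are derived from
#'   \code{config$seed}.
#' @param ... passed to [seqrisk_fit()].
#' @return object of class \code{metrics_report}: list with
#'   \code{per_repeat} (5 x k metric matrix), \code{mean}, \code{sd} and
#'   \code{model}.
#' @export
repeat_runs <- function(data, model = "retain", k = 5, config = model_config(),
                        ...) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  metric_names <- c("validation_auroc", "test_auroc", "test_precision",
                    "test_recall", "test_f1")
  M <- matrix(NA_real_, length(metric_names), k,
              dimnames = list(metric_names, paste0("run", seq_len(k))))
  for (r in seq_len(k)) {
    cfg_r <- config
    cfg_r$seed <- child_seed(config$seed, r)
    fit <- seqrisk_fit(data, model = model, config = cfg_r, ...)
    M[, r] <- c(fit$metrics[["validation_auroc"]], fit$metrics[["test_auroc"]],
                fit$metrics[["precision"]], fit$metrics[["recall"]],
                fit$metrics[["f1"]])
  }
  structure(list(per_repeat = M, mean = rowMeans(M),
                 sd = apply(M, 1, sd), model = model),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics over %d repeats (%s):\n", ncol(x$per_repeat),
              toupper(x$model)))
  print(round(cbind(x$per_repeat, Average = x$mean, std.s = x$sd), 4))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  df <- as.data.frame(cbind(x$per_repeat, Average = x$mean, std.s = x$sd))
  cbind(data.frame(Metric = rownames(df), stringsAsFactors = FALSE), df,
        row.names = NULL)
}

#' Write a metrics report to CSV
#'
#' One row per metric (validation AUROC, test AUROC, test precision, test
#' recall, test F1), one column per repeat, plus \code{Average} and
#' \code{std.s} columns.
#'
#' @param report a \code{metrics_report}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_metrics_csv <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
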