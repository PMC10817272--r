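#' Fit a sequence risk classifier
#'
#' Trains one of three classifiers on an encoded cohort: \code{"tlstm"}
#' (stacked time-aware LSTM over visit sequences), \code{"retain"}
#' (reverse-time two-level attention) or \code{"lr"} (logistic regression
#' on bag-of-token counts plus continuous SDoH covariates). The deep models
#' are trained with per-sample Adam updates on binary cross-entropy;
#' training stops early when validation AUROC fails to improve for
#' \code{patience} consecutive epochs and the best-validation weights are
#' returned.
#'
#' @param data an \code{encoded_cohort} from [encode_cohort()].
#' @param model \code{"tlstm"}, \code{"retain"} or \code{"lr"}.
#' @param config a [model_config()]; its \code{seed} drives weight
#'   initialization, dropout and shuffling.
#' @param split list with integer index vectors \code{train},
#'   \code{validation}, \code{test} (see [split_samples()]); by default an
#'   8:1:1 split seeded from \code{config$seed}.
#' @param max_epochs maximum training epochs (deep models).
#' @param patience epochs without validation improvement before stopping
#'   (default 3).
#' @param learn_rate Adam learning rate.
#' @param verbose print per-epoch progress.
#' @return object of class \code{seqrisk_model} with elements
#'   \code{model}, \code{params} (or \code{coefficients} for \code{"lr"}),
#'   \code{config}, \code{split}, \code{history}, \code{metrics} (test-set
#'   metrics of the returned weights) and \code{vocab_size}.
#' @seealso [predict.seqrisk_model()], [evaluate_model()], [repeat_runs()]
#' @export
seqrisk_fit <- function(data, model = c("retain", "tlstm", "lr"),
                        config = model_config(), split = NULL,
                        max_epochs = 20, patience = 3, learn_rate = 0.01,
                        verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(data, "encoded_cohort"))
  n <- length(data$samples)
  if (is.null(split)) split <- split_samples(n, seed = config$seed)
  y <- data$labels

  if (model == "lr") {
    fit <- fit_lr(data, split$train)
    obj <- structure(list(model = "lr", coefficients = fit$coefficients,
                          feature_names = fit$feature_names, config = config,
                          split = split, history = NULL,
                          vocab_size = length(data$vocab$tokens)),
                     class = "seqrisk_model")
  } else {
    vocab_size <- length(data$vocab$tokens)
    params <- nn_init(model, vocab_size, config)
    state <- adam_init(params)
    set.seed(child_seed(config$seed, 977L))
    best <- list(auc = -Inf, params = params, epoch = 0L)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_auroc = numeric(0))
    stall <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(split$train)
      tot_loss <- 0
      for (i in ord) {
        s <- data$samples[[i]]
        masks <- make_masks(model, length(s$visits), config)
        gr <- if (model == "tlstm")
          tlstm_grad(s$visits, s$elapsed, y[i], params, config,
                     masks = masks$m)
        else retain_grad(s$visits, y[i], params, config,
                         masks_a = masks$ma, masks_b = masks$mb)
        if (!is.finite(gr$loss))
          stop("divergent loss (non-finite); lower the learning rate",
               call. = FALSE)
        tot_loss <- tot_loss + gr$loss
        up <- adam_step(params, gr$grads, state, lr = learn_rate)
        params <- up$params; state <- up$state
      }
      val_p <- predict_encoded(model, params, config, data, split$validation)
      val_auc <- auroc(val_p, y[split$validation])
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = tot_loss / length(ord),
                                     val_auroc = val_auc))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val AUROC %.4f",
                        epoch, tot_loss / length(ord), val_auc))
      if (val_auc > best$auc) {
        best <- list(auc = val_auc, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    obj <- structure(list(model = model, params = best$params,
                          config = config, split = split, history = hist,
                          best_epoch = best$epoch,
                          vocab_size = vocab_size),
                     class = "seqrisk_model")
  }
  test_p <- predict(obj, data, indices = split$test)
  obj$metrics <- c(
    validation_auroc = auroc(predict(obj, data, indices = split$validation),
                             y[split$validation]),
    test_auroc = auroc(test_p, y[split$test]),
    classification_metrics(test_p, y[split$test])
  )
  obj
}

make_masks <- function(model, Tn, config) {
  p <- config$dropout
  if (p <= 0) return(list(m = NULL, ma = NULL, mb = NULL))
  h <- config$hidden_size
  mk <- function(L) lapply(seq_len(L), function(l)
    matrix(rbinom(Tn * h, 1, 1 - p) / (1 - p), Tn, h))
  if (model == "tlstm") list(m = mk(config$n_layers), ma = NULL, mb = NULL)
  else {
    la <- max(1L, config$n_layers %/% 2L)
    lb <- max(1L, config$n_layers - la)
    list(m = NULL, ma = mk(la), mb = mk(lb))
  }
}

# logistic-regression baseline: token counts + continuous covariates
fit_lr <- function(data, train_idx) {
  X <- count_matrix(data)
  Xt <- X[train_idx, , drop = FALSE]
  keep <- colSums(Xt != 0, na.rm = TRUE) > 0
  Xt <- Xt[, keep, drop = FALSE]
  df <- as.data.frame(Xt)
  names(df) <- paste0("f", seq_len(ncol(Xt)))
  df$.y <- data$labels[train_idx]
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  coefs <- coef(fit)
  coefs[is.na(coefs)] <- 0
  full <- setNames(numeric(ncol(X) + 1), c("(Intercept)", colnames(X)))
  full["(Intercept)"] <- coefs[["(Intercept)"]]
  full[colnames(X)[keep]] <- coefs[-1]
  list(coefficients = full, feature_names = colnames(X))
}

count_matrix <- function(data) {
  V <- length(data$vocab$tokens)
  n <- length(data$samples)
  X <- matrix(0, n, V)
  for (i in seq_len(n)) {
    ix <- unlist(data$samples[[i]]$visits, use.names = FALSE)
    tb <- tabulate(ix, nbins = V)
    X[i, ] <- tb
  }
  colnames(X) <- data$vocab$tokens
  cov <- data$covariates
  if (!is.null(cov) && ncol(cov)) {
    cov[is.na(cov)] <- 0
    colnames(cov) <- paste0("cov_", colnames(data$covariates))
    X <- cbind(X, cov)
  }
  X
}

#' Logistic scoring of a feature vector
#'
#' Standard logistic-regression forward pass: the probability is
#' \code{plogis(intercept + sum(coefficients * features))}.
#'
#' @param features named or positional numeric vector (token counts plus
#'   covariates); all values must be finite.
#' @param coefficients numeric vector aligned with \code{features}.
#' @param intercept scalar intercept.
#' @return probability in (0, 1).
#' @export
lr_forward <- function(features, coefficients, intercept = 0) {
  if (any(!is.finite(features))) stop("features must be finite", call. = FALSE)
  plogis(intercept + sum(coefficients * features))
}

predict_encoded <- function(model, params, config, data, indices) {
  vapply(indices, function(i) {
    s <- data$samples[[i]]
    if (model == "tlstm")
      tlstm_forward(s$visits, s$elapsed, params, config)$probability
    else retain_forward(s$visits, params, config)$probability
  }, numeric(1))
}

#' Predict risk probabilities from a fitted model
#'
#' @param object a \code{seqrisk_model}.
#' @param newdata an \code{encoded_cohort} (same vocabulary as used for
#'   fitting).
#' @param indices optional integer subset of samples to score.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.seqrisk_model <- function(object, newdata, indices = NULL, ...) {
  stopifnot(inherits(newdata, "encoded_cohort"))
  if (is.null(indices)) indices <- seq_along(newdata$samples)
  if (object$model == "lr") {
    X <- count_matrix(newdata)
    co <- object$coefficients
    eta <- co[["(Intercept)"]] +
      as.vector(X[indices, , drop = FALSE] %*% co[colnames(X)])
    return(plogis(eta))
  }
  predict_encoded(object$model, object$params, object$config, newdata, indices)
}

#' @export
coef.seqrisk_model <- function(object, ...) {
  if (object$model != "lr")
    stop("coefficients are only defined for the logistic-regression model",
         call. = FALSE)
  object$coefficients
}

#' @export
print.seqrisk_model <- function(x, ...) {
  cat(sprintf("seqrisk %s model (vocab %d", toupper(x$model), x$vocab_size))
  if (!is.null(x$history))
    cat(sprintf(", %d epochs, best epoch %d", nrow(x$history), x$best_epoch))
  cat(")\n")
  if (!is.null(x$metrics))
    cat(sprintf("  test AUROC %.3f, precision %.3f, recall %.3f, F1 %.3f\n",
                x$metrics[["test_auroc"]], x$metrics[["precision"]],
                x$metrics[["recall"]], x$metrics[["f1"]]))
  invisible(x)
}

#' @export
summary.seqrisk_model <- function(object, ...) {
  structure(list(model = object$model, metrics = object$metrics,
                 history = object$history,
                 split_sizes = lengths(object$split)),
            class = "summary.seqrisk_model")
}

#' @export
print.summary.seqrisk_model <- function(x, ...) {
  cat(sprintf("Model: %s\nSplit sizes (train/validation/test): %s\n",
              toupper(x$model), paste(x$split_sizes, collapse = "/")))
  if (!is.null(x$metrics)) {
    cat("Metrics:\n")
    print(round(x$metrics, 4))
  }
  if (!is.null(x$history)) {
    cat("Training history (last rows):\n")
    print(utils::tail(x$history, 3), row.names = FALSE)
  }
  invisible(x)
}

#' Plot training history of a fitted deep model
#' @param x a \code{seqrisk_model}.
#' @param ... passed to \code{plot}.
#' @export
plot.seqrisk_model <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot", call. = FALSE)
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)), add = TRUE)
  plot(x$history$epoch, x$history$train_loss, type = "b", xlab = "epoch",
       ylab = "training loss", ...)
  plot(x$history$epoch, x$history$val_auroc, type = "b", xlab = "epoch",
       ylab = "validation AUROC", ...)
  invisible(x)
}
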