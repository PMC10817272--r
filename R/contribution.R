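# Perturbation-based relative-contribution analysis: per-patient feature
# contributions (FC) by token-deletion occlusion, per-patient
# normalization, median-ratio relative contribution (RC) with reference
# scaling, Wilcoxon significance and Benjamini-Hochberg FDR control.

predict_sample <- function(object, sample, covariate_row = NULL) {
  if (object$model == "lr") {
    V <- object$vocab_size
    counts <- tabulate(unlist(sample$visits, use.names = FALSE), nbins = V)
    co <- object$coefficients
    x <- counts
    if (!is.null(covariate_row)) {
      covariate_row[is.na(covariate_row)] <- 0
      x <- c(x, covariate_row)
    }
    return(plogis(co[[1]] + sum(co[-1][seq_along(x)] * x)))
  }
  if (!length(sample$visits)) {
    b <- if (object$model == "tlstm") object$params$b_out else object$params$b_out
    return(sigmoid(b))  # no-information prediction: zero hidden state / context
  }
  if (object$model == "tlstm")
    tlstm_forward(sample$visits, sample$elapsed, object$params,
                  object$config)$probability
  else retain_forward(sample$visits, object$params, object$config)$probability
}

# remove token index from given visits (all occurrences in `which_visits`),
# dropping emptied visits and recomputing elapsed gaps
remove_token <- function(sample, token_ix, which_visits = NULL) {
  visits <- sample$visits
  tgt <- if (is.null(which_visits)) seq_along(visits) else which_visits
  for (t in tgt) visits[[t]] <- visits[[t]][visits[[t]] != token_ix]
  keep <- lengths(visits) > 0
  db <- sample$days_before[keep]
  list(visits = visits[keep],
       elapsed = if (length(db)) c(0, -diff(db)) else numeric(0),
       days_before = db)
}

#' Raw perturbation feature contribution for one patient
#'
#' The contribution of a token is the change in predicted risk when its
#' occurrences are deleted from the visit sequence and the forward pass is
#' recomputed: \code{FC = p(full) - p(without token)}. With
#' \code{mode = "per_occurrence"} each visit's occurrence is deleted one at
#' a time and the deltas are summed, totalling the feature's value within
#' the patient; the default \code{"all"} deletes every occurrence at once.
#'
#' @param object a fitted \code{seqrisk_model}.
#' @param data an \code{encoded_cohort}.
#' @param index sample index within \code{data}.
#' @param token token string (must occur in the sample).
#' @param mode \code{"all"} or \code{"per_occurrence"}.
#' @return a single numeric FC value.
#' @export
feature_contribution <- function(object, data, index, token,
                                 mode = c("all", "per_occurrence")) {
  mode <- match.arg(mode)
  s <- data$samples[[index]]
  ix <- vocab_lookup(data$vocab, token)
  if (is.na(ix) || !any(vapply(s$visits, function(v) ix %in% v, logical(1))))
    stop(sprintf("token '%s' does not occur in sample %d", token, index),
         call. = FALSE)
  cov_row <- if (!is.null(data$covariates)) data$covariates[index, ] else NULL
  p_full <- predict_sample(object, s, cov_row)
  if (mode == "all") {
    p_mod <- predict_sample(object, remove_token(s, ix), cov_row)
    return(p_full - p_mod)
  }
  hits <- which(vapply(s$visits, function(v) ix %in% v, logical(1)))
  sum(vapply(hits, function(t) {
    p_full - predict_sample(object, remove_token(s, ix, t), cov_row)
  }, numeric(1)))
}

#' Normalize one patient's raw feature contributions
#'
#' Each raw FC is divided by the sum of absolute raw FCs of all the
#' patient's features, so contributions are comparable across patients with
#' different encounter volumes. Numerators keep their sign; if all raw FCs
#' are zero the normalized values are all zero.
#'
#' @param raw named numeric vector of raw FC values for one patient.
#' @return named numeric vector; \code{sum(abs(result))} is 1 whenever any
#'   raw value is nonzero.
#' @export
normalize_fc <- function(raw) {
  if (!length(raw)) stop("need at least one feature contribution", call. = FALSE)
  denom <- sum(abs(raw))
  if (denom == 0) return(raw * 0)
  raw / denom
}

#' Median-ratio relative contribution
#'
#' \code{RC = median(FC of cases) / median(FC of controls)}. A zero
#' control median makes the ratio undefined and returns \code{NA} (the
#' token is still reported, with support counts and p value).
#'
#' @param fc_cases,fc_controls numeric vectors of normalized FC values
#'   (both non-empty).
#' @return a single numeric RC, or \code{NA} if undefined.
#' @export
rc_value <- function(fc_cases, fc_controls) {
  if (!length(fc_cases) || !length(fc_controls))
    stop("both FC lists must be non-empty", call. = FALSE)
  md <- median(fc_controls)
  if (md == 0) return(NA_real_)
  median(fc_cases) / md
}

#' Scale relative contributions to a reference feature
#'
#' Multiplies every RC by \code{1 / RC(reference)} so the reference token
#' (the grouped PTSD diagnosis) has RC exactly 1. After scaling, RC > 1
#' marks a risk-associated feature and RC < 1 a protective one.
#'
#' @param rc named numeric vector of raw RC values.
#' @param reference_token name of the reference feature (must have a
#'   defined, nonzero RC).
#' @return named numeric vector of scaled RCs.
#' @export
scale_rc <- function(rc, reference_token) {
  ref <- if (reference_token %in% names(rc)) rc[[reference_token]] else NA_real_
  if (is.na(ref) || ref == 0)
    stop(sprintf("reference token '%s' has no defined RC", reference_token),
         call. = FALSE)
  out <- rc / ref
  out[[reference_token]] <- 1
  out
}

#' Wilcoxon rank-sum significance of a feature's contribution difference
#'
#' Two-sided rank-sum p value comparing the feature's normalized FC values
#' among cases against controls (exact enumeration for small samples, see
#' [rank_sum_test()]).
#'
#' @param fc_cases,fc_controls numeric FC vectors (both non-empty).
#' @return p value.
#' @export
rc_significance <- function(fc_cases, fc_controls) {
  rank_sum_test(fc_cases, fc_controls)$p.value
}

#' Perturbation-based feature report
#'
#' For every vocabulary token with at least \code{min_support} carriers in
#' each class: computes per-patient normalized FCs, the scaled median-ratio
#' RC, the Wilcoxon rank-sum p value, the Benjamini-Hochberg q value and
#' the case/control support counts. Rows are ranked by q ascending, then
#' total support descending, then token name.
#'
#' @param object a fitted \code{seqrisk_model}.
#' @param data an \code{encoded_cohort} (both classes present).
#' @param indices sample indices to analyse (default: all samples).
#' @param min_support minimum number of carriers per class (default 10).
#' @param mode FC aggregation mode (see [feature_contribution()]).
#' @param alpha FDR level for the significance flags (default 0.05).
#' @return object of class \code{feature_report}: data frame with columns
#'   \code{Feature}, \code{RelativeContribution}, \code{Wilcoxon_p},
#'   \code{FDR_Q}, \code{CaseSupport}, \code{ControlSupport},
#'   \code{Significant}.
#' @export
feature_report <- function(object, data, indices = NULL, min_support = 10,
                           mode = c("all", "per_occurrence"), alpha = 0.05) {
  mode <- match.arg(mode)
  if (is.null(indices)) indices <- seq_along(data$samples)
  y <- data$labels[indices]
  if (length(unique(y)) < 2)
    stop("contribution analysis needs both classes", call. = FALSE)

  V <- length(data$vocab$tokens)
  fc_case <- vector("list", V); fc_ctrl <- vector("list", V)
  for (k in seq_along(indices)) {
    i <- indices[k]
    s <- data$samples[[i]]
    toks <- unique(unlist(s$visits, use.names = FALSE))
    if (!length(toks)) next
    cov_row <- if (!is.null(data$covariates)) data$covariates[i, ] else NULL
    p_full <- predict_sample(object, s, cov_row)
    raw <- vapply(toks, function(ix) {
      if (mode == "all")
        p_full - predict_sample(object, remove_token(s, ix), cov_row)
      else {
        hits <- which(vapply(s$visits, function(v) ix %in% v, logical(1)))
        sum(vapply(hits, function(t)
          p_full - predict_sample(object, remove_token(s, ix, t), cov_row),
          numeric(1)))
      }
    }, numeric(1))
    nfc <- normalize_fc(raw)
    for (j in seq_along(toks)) {
      ix <- toks[j]
      if (y[k] == 1) fc_case[[ix]] <- c(fc_case[[ix]], nfc[j])
      else fc_ctrl[[ix]] <- c(fc_ctrl[[ix]], nfc[j])
    }
  }

  ncase <- lengths(fc_case); nctrl <- lengths(fc_ctrl)
  keep <- which(ncase >= min_support & nctrl >= min_support)
  ref <- data$reference_token
  ref_ix <- vocab_lookup(data$vocab, ref)
  if (is.na(ref_ix) || !(ref_ix %in% keep))
    stop(sprintf("reference token '%s' lacks sufficient support", ref),
         call. = FALSE)

  rc_raw <- vapply(keep, function(ix) rc_value(fc_case[[ix]], fc_ctrl[[ix]]),
                   numeric(1))
  names(rc_raw) <- vocab_decode(data$vocab, keep)
  rc_scaled <- scale_rc(rc_raw, ref)
  p <- vapply(keep, function(ix) rc_significance(fc_case[[ix]], fc_ctrl[[ix]]),
              numeric(1))
  adj <- fdr_adjust(p, alpha = alpha)

  out <- data.frame(
    Feature = names(rc_raw),
    RelativeContribution = unname(rc_scaled),
    Wilcoxon_p = p,
    FDR_Q = adj$q,
    CaseSupport = unname(ncase[keep]),
    ControlSupport = unname(nctrl[keep]),
    Significant = adj$significant,
    stringsAsFactors = FALSE
  )
  ord <- order(out$FDR_Q, -(out$CaseSupport + out$ControlSupport), out$Feature)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_report", "data.frame")
  out
}

#' Write a feature report to CSV (relative-contribution table layout)
#' @param report a [feature_report()] result.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_feature_report <- function(report, path) {
  cols <- c("Feature", "RelativeContribution", "Wilcoxon_p", "FDR_Q",
            "CaseSupport", "ControlSupport")
  write.csv(as.data.frame(report)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Repeated-split SDoH coefficient analysis
#'
#' Refits the logistic-regression model on \code{repeats} re-randomized
#' 8:1:1 splits and summarizes the coefficients of the continuous SDoH
#' covariates (and therapy flags): mean, sample standard deviation and the
#' two-sided one-sample t-test p value of the mean against zero
#' (\code{df = repeats - 1}). A zero standard deviation makes the t test
#' degenerate; such rows get \code{NA} p values and are marked in the
#' direction sentence.
#'
#' @param data an \code{encoded_cohort} with covariates.
#' @param repeats number of refits (default 10).
#' @param seed base seed; per-repeat split seeds derive from it.
#' @return object of class \code{sdoh_report}: data frame with columns
#'   \code{Name}, \code{Mean}, \code{sd}, \code{p}, \code{Direction}.
#' @export
sdoh_coefficient_analysis <- function(data, repeats = 10, seed = 1L) {
  if (is.null(data$covariates) || !ncol(data$covariates))
    stop("no SDoH covariates in the encoded cohort", call. = FALSE)
  cov_names <- paste0("cov_", colnames(data$covariates))
  n <- length(data$samples)
  M <- matrix(NA_real_, repeats, length(cov_names),
              dimnames = list(NULL, cov_names))
  for (r in seq_len(repeats)) {
    sp <- split_samples(n, seed = child_seed(seed, r))
    fit <- fit_lr(data, sp$train)
    M[r, ] <- fit$coefficients[cov_names]
  }
  mu <- colMeans(M)
  sdv <- apply(M, 2, sd)
  p <- ifelse(sdv > 0,
              2 * pt(-abs(mu / (sdv / sqrt(repeats))), df = repeats - 1),
              NA_real_)
  dir <- ifelse(sdv == 0, "degenerate: zero variance across repeats",
    ifelse(mu > 0,
           "higher values associated with higher predicted risk",
           "higher values associated with lower predicted risk"))
  out <- data.frame(Name = sub("^cov_", "", cov_names), Mean = unname(mu),
                    sd = unname(sdv), p = unname(p), Direction = dir,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sdoh_report", "data.frame")
  out
}

#' Write an SDoH coefficient report to CSV
#' @param report an [sdoh_coefficient_analysis()] result.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_sdoh_report <- function(report, path) {
  write.csv(as.data.frame(report)[, c("Name", "Mean", "sd", "p", "Direction")],
            path, row.names = FALSE)
  invisible(path)
}
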