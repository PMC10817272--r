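# a two-token logistic model whose removal deltas have closed forms
lr_fixture <- function() {
  vocab <- build_vocab(list(c("A", "A", "B")), reference_token = "A")
  samples <- list(
    list(patient_id = "P1", label = 1L,
         visits = list(c(1L, 1L, 2L), 1L), elapsed = c(0, 5),
         days_before = c(5, 0), static_tokens = character(0)),
    list(patient_id = "P2", label = 0L,
         visits = list(2L), elapsed = 0, days_before = 0,
         static_tokens = character(0)))
  enc <- structure(list(samples = samples, vocab = vocab, covariates = NULL,
                        labels = c(1L, 0L), dropped_rx = 0L,
                        reference_token = "A"), class = "encoded_cohort")
  co <- setNames(c(-0.5, 0.8, -0.4), c("(Intercept)", "A", "B"))
  fit <- structure(list(model = "lr", coefficients = co,
                        feature_names = c("A", "B"),
                        config = model_config(seed = 1),
                        split = NULL, vocab_size = 2L),
                   class = "seqrisk_model")
  list(enc = enc, fit = fit)
}

test_that("feature contribution equals the closed-form removal delta", {
  fx <- lr_fixture()
  # P1 carries token A in two visits (count 3) and B once
  p_full <- plogis(-0.5 + 3 * 0.8 - 0.4)
  expect_equal(feature_contribution(fx$fit, fx$enc, 1, "A"),
               p_full - plogis(-0.5 - 0.4))
  expect_equal(feature_contribution(fx$fit, fx$enc, 1, "B"),
               p_full - plogis(-0.5 + 3 * 0.8))
  # per-occurrence deltas sum over the two visits carrying A
  d1 <- p_full - plogis(-0.5 + 1 * 0.8 - 0.4)  # drop visit-1 occurrences (2 copies)
  d2 <- p_full - plogis(-0.5 + 2 * 0.8 - 0.4)  # drop visit-2 occurrence
  expect_equal(feature_contribution(fx$fit, fx$enc, 1, "A",
                                    mode = "per_occurrence"), d1 + d2)
  expect_error(feature_contribution(fx$fit, fx$enc, 2, "A"), "does not occur")
})

test_that("a token the model ignores contributes exactly zero", {
  fx <- lr_fixture()
  fx$fit$coefficients[["B"]] <- 0
  expect_equal(feature_contribution(fx$fit, fx$enc, 1, "B"), 0)
})

test_that("per-patient normalization conserves signed shares", {
  expect_equal(normalize_fc(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(normalize_fc(c(0, 0)), c(0, 0))
  expect_equal(normalize_fc(c(-1, 3)), c(-0.25, 0.75))
  expect_error(normalize_fc(numeric(0)), "at least one")
  set.seed(2)
  for (rep in 1:25) {
    raw <- rnorm(sample(1:8, 1)) * sample(c(0, 1), 1)
    nf <- normalize_fc(raw)
    if (any(raw != 0)) expect_equal(sum(abs(nf)), 1)
    else expect_true(all(nf == 0))
  }
})

test_that("median-ratio RC matches hand arithmetic and guards zero medians", {
  expect_equal(rc_value(c(0.2, 0.4, 0.6), c(0.1, 0.2, 0.3)), 2)
  expect_equal(rc_value(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_true(is.na(rc_value(c(1, 2), c(-1, 1))))
  expect_error(rc_value(numeric(0), 1), "non-empty")
})

test_that("reference scaling fixes the reference RC at exactly 1", {
  expect_equal(scale_rc(c(PTSD = 0.8, X = 1.6), "PTSD"),
               c(PTSD = 1, X = 2))
  expect_equal(scale_rc(c(PTSD = 1, X = 0.5), "PTSD"), c(PTSD = 1, X = 0.5))
  expect_error(scale_rc(c(X = 0.5), "PTSD"), "no defined RC")
  expect_error(scale_rc(c(PTSD = NA, X = 0.5), "PTSD"), "no defined RC")
  set.seed(4)
  for (rep in 1:20) {
    rc <- setNames(runif(6, 0.1, 3), paste0("t", 1:6))
    out <- scale_rc(rc, "t3")
    expect_identical(out[["t3"]], 1)
    expect_equal(out[["t1"]] / out[["t2"]], rc[["t1"]] / rc[["t2"]])
  }
})

test_that("rc significance is the two-sided rank-sum p value", {
  expect_equal(rc_significance(c(1, 2), c(3, 4)), 1 / 3)
  x <- rnorm(12); y <- rnorm(15)
  expect_equal(rc_significance(x, y), rank_sum_test(x, y)$p.value)
})

test_that("feature report has the published table shape and ordering", {
  enc <- small_encoded(n = 250, seed = 71)
  fit <- seqrisk_fit(enc, "lr", model_config(seed = 6))
  fr <- feature_report(fit, enc, min_support = 10)
  expect_s3_class(fr, "feature_report")
  expect_identical(names(fr)[1:6],
                   c("Feature", "RelativeContribution", "Wilcoxon_p", "FDR_Q",
                     "CaseSupport", "ControlSupport"))
  expect_equal(fr$RelativeContribution[fr$Feature == "DX:F43"], 1)
  expect_true(all(diff(fr$FDR_Q) >= -1e-12))
  expect_true(all(fr$CaseSupport >= 10 & fr$ControlSupport >= 10))
  path <- file.path(tempdir(), "fr.csv")
  write_feature_report(fr, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("Feature", "RelativeContribution", "Wilcoxon_p", "FDR_Q",
                     "CaseSupport", "ControlSupport"))
})

test_that("sdoh coefficient analysis reports t-tests over repeated refits", {
  # arithmetic oracle for the t statistic on a known coefficient series
  co <- c(0.10, 0.12, 0.11, 0.13, 0.09, 0.12, 0.10, 0.11, 0.13, 0.09)
  expect_equal(mean(co), 0.11)
  expect_equal(sd(co), 0.0149, tolerance = 1e-3)
  tt <- mean(co) / (sd(co) / sqrt(10))
  expect_equal(tt, 23.33, tolerance = 1e-2)
  p <- 2 * pt(-abs(tt), df = 9)
  expect_lt(p, 1e-8)
  expect_equal(p, stats::t.test(co, mu = 0)$p.value, tolerance = 1e-10)

  enc <- small_encoded(n = 600, seed = 73)
  rep <- sdoh_coefficient_analysis(enc, repeats = 5, seed = 3)
  expect_s3_class(rep, "sdoh_report")
  expect_identical(names(rep), c("Name", "Mean", "sd", "p", "Direction"))
  expect_true(all(rep$sd >= 0))
  # planted neighborhood-SES coefficient recovered with the right sign
  expect_lt(rep$Mean[rep$Name == "nses"], 0)
  expect_lt(rep$p[rep$Name == "nses"], 0.05)
  path <- file.path(tempdir(), "sdoh.csv")
  write_sdoh_report(rep, path)
  expect_identical(names(read.csv(path)),
                   c("Name", "Mean", "sd", "p", "Direction"))
})

test_that("degenerate zero-variance coefficients get a sentinel, not p = 0", {
  # direct check of the degenerate branch arithmetic
  M <- matrix(0.1, 3, 1)
  sdv <- apply(M, 2, sd)
  expect_equal(sdv, 0)
  p <- ifelse(sdv > 0, 2 * pt(-abs(0.1 / (sdv / sqrt(3))), 2), NA_real_)
  expect_true(is.na(p))
})
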